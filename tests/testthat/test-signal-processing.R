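test_that("LRR and BAF formulas satisfy their identities", {
  expect_identical(compute_lrr(2, 2), 0)
  expect_identical(compute_lrr(1, 2), -1)
  expect_equal(compute_lrr(3, 2), log2(1.5))
  for (x in c(0.1, 1, 7, 123.4)) {
    expect_equal(compute_lrr(x, x), 0)
    expect_equal(compute_lrr(2 * x, x), 1)
  }
  expect_error(compute_lrr(0, 1), "positive")
  expect_error(compute_lrr(1, -2), "positive")

  expect_identical(compute_baf(5, 0), 0)
  expect_identical(compute_baf(0, 5), 1)
  expect_equal(compute_baf(3, 3), 0.5)
  expect_equal(compute_baf(1, 3), 0.75)
  set.seed(1)
  a <- runif(50, 0, 10); b <- runif(50, 0, 10)
  expect_equal(compute_baf(a, b) + compute_baf(b, a), rep(1, 50))
  expect_error(compute_baf(0, 0), "uncallable")
  expect_error(compute_baf(-1, 2), ">= 0")
})

test_that("filter_probes matches the per-record predicate oracle and is idempotent", {
  s <- make_signals(c("chr1", "chr1", "chrY", "chr2", "Y", "chr2",
                      "chr3", "chr3", "chr1", "chr2"),
                    pos = 1:10 * 100,
                    genotype = c("AA", "AB", "AB", "NC", "BB", "BB",
                                 "AB", "AA", "BB", "AB"))
  out <- filter_probes(s)
  oracle <- s[!(s$chrom %in% c("chrY", "Y")) & s$genotype != "NC", ]
  rownames(oracle) <- NULL
  expect_identical(out, oracle)
  expect_equal(nrow(out), 7)
  expect_identical(filter_probes(out), out)        # idempotent
  expect_equal(nrow(filter_probes(make_signals("chrY", 1:5))), 0)
  # order preserved
  expect_identical(out$probe_id, s$probe_id[!(s$chrom %in% c("chrY", "Y")) &
                                              s$genotype != "NC"])
})

test_that("combine_replicates averages signals and resolves genotypes", {
  s <- make_signals("chr1", 1:4 * 100, lrr = c(0.2, -0.2, 1, 0),
                    baf = c(0.4, 0.6, 0.5, 1), genotype = "AB")
  expect_identical(combine_replicates(list(s, s))$lrr, s$lrr)

  r1 <- s; r2 <- s; r3 <- s
  r1$lrr <- rep(0.2, 4); r2$lrr <- rep(-0.2, 4)
  expect_equal(combine_replicates(list(r1, r2))$lrr, rep(0, 4))
  r1$baf <- rep(0.4, 4); r2$baf <- rep(0.6, 4); r3$baf <- rep(0.5, 4)
  expect_equal(combine_replicates(list(r1, r2, r3))$baf, rep(0.5, 4))

  r2$genotype <- c("AB", "AA", "AB", "AB")
  expect_equal(combine_replicates(list(r1, r2))$genotype,
               c("AB", "NC", "AB", "AB"))
  r_bad <- s[1:3, ]
  expect_error(combine_replicates(list(s, r_bad)), "share the probe set")
})

test_that("gc_correct removes a linear GC wave and preserves the grand mean", {
  set.seed(2)
  gc <- runif(200)
  s <- make_signals("chr1", seq_len(200) * 100,
                    lrr = 0.5 * (gc - 0.5), gc = gc)
  corrected <- gc_correct(s)
  expect_equal(corrected$lrr, rep(mean(s$lrr), 200), tolerance = 1e-9)
  expect_equal(mean(corrected$lrr), mean(s$lrr), tolerance = 1e-9)

  # additive equivariance and BAF untouched
  noisy <- s
  noisy$lrr <- s$lrr + rnorm(200, 0, 0.1)
  c1 <- gc_correct(noisy)
  shifted <- noisy
  shifted$lrr <- noisy$lrr + 3
  c2 <- gc_correct(shifted)
  expect_equal(c2$lrr, c1$lrr + 3, tolerance = 1e-9)
  expect_identical(c1$baf, noisy$baf)
  expect_equal(mean(c1$lrr), mean(noisy$lrr), tolerance = 1e-9)

  flat <- s
  flat$gc <- 0.4
  expect_warning(out <- gc_correct(flat), "constant")
  expect_identical(out$lrr, flat$lrr)
  expect_error(gc_correct(s[1:2, ]), ">= 3 probes")
})

test_that("pair_adjust subtracts normal from tumor on a matched probe set", {
  t <- make_signals("chr1", 1:5 * 100, lrr = c(-1, 0, 1, 0.5, 0),
                    baf = c(0, 0.5, 1, 0.5, 0.5))
  n <- make_signals("chr1", 1:5 * 100, lrr = c(0.1, 0, -0.1, 0.5, 0),
                    genotype = c("AA", "AB", "BB", "AB", "NC"))
  p <- pair_adjust(t, n)
  expect_equal(p$lrr, t$lrr - n$lrr)
  expect_equal(p$lrr[1], -1.1)
  expect_identical(p$baf, t$baf)                 # tumor BAF carried
  expect_identical(p$genotype, n$genotype)       # normal genotype carried
  expect_equal(pair_adjust(t, t)$lrr, rep(0, 5))
  # order invariance
  perm <- sample(5)
  expect_identical(pair_adjust(t[perm, ], n), p)
  expect_error(pair_adjust(t, n[1:4, ]), "probe sets differ")
})

test_that("quality_score is a robust per-probe noise estimate", {
  expect_equal(quality_score(make_signals("chr1", 1:50, lrr = 0.3)), 0)
  d <- 0.25
  alt <- make_signals("chr1", 1:40, lrr = rep(c(d, -d), 20))
  expect_equal(quality_score(alt), d * sqrt(2))   # median |2d| / sqrt(2)
  set.seed(3)
  g <- make_signals("chr1", seq_len(1e5), lrr = rnorm(1e5, 0, 0.2))
  expect_equal(quality_score(g), 0.674 * 0.2, tolerance = 0.02)
  # a step change (real CNV) barely moves the robust score
  stepped <- g
  stepped$lrr[5e4:1e5] <- stepped$lrr[5e4:1e5] - 1
  expect_equal(quality_score(stepped), quality_score(g), tolerance = 0.01)
  expect_error(quality_score(make_signals("chr1", 1)), ">= 2 probes")
  expect_warning(quality_score(g, warn_above = 0.02), "exceeds")
})
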