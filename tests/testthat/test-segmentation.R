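test_that("mirrored_baf_deviation measures allelic imbalance", {
  expect_equal(mirrored_baf_deviation(rep(0.5, 10)), 0)
  expect_equal(mirrored_baf_deviation(c(0, 1, 0, 1)), 0.5)
  expect_equal(mirrored_baf_deviation(c(0.33, 0.67)), 0.17)
  expect_true(is.na(mirrored_baf_deviation(numeric(0))))
})

test_that("segment_signal finds noiseless steps exactly and matches the scan oracle", {
  expect_identical(segment_signal(rep(0.3, 100)), integer(0))
  expect_identical(segment_signal(rnorm(6), min_probes = 5), integer(0))

  step <- c(rep(0, 100), rep(-1, 100))
  expect_identical(segment_signal(step, t_threshold = 5), 100L)
  expect_equal(oracle_best_split(step, 5)$index, 100L)

  set.seed(7)
  x <- c(rnorm(80, 0, 0.1), rnorm(60, -1, 0.1), rnorm(90, 0, 0.1))
  bp <- segment_signal(x, t_threshold = 5)
  expect_equal(length(bp), 2)
  expect_true(abs(bp[1] - 80) <= 2 && abs(bp[2] - 140) <= 2)
  # first accepted split equals the exhaustive scan's maximizer
  expect_equal(oracle_best_split(x, 5)$index %in% bp, TRUE)
})

test_that("raising the stopping threshold never adds breakpoints", {
  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(150, 0, 0.2) +
      rep(sample(c(-1, 0, 0.6), 3), times = c(50, 60, 40))
    prev <- segment_signal(x, t_threshold = 2)
    for (T in c(4, 6, 10, 20)) {
      cur <- segment_signal(x, t_threshold = T)
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("classify_segment applies thresholds with precedence", {
  expect_equal(classify_segment(0, 0), "neutral")
  expect_equal(classify_segment(-1.3, NA), "homozygous_loss")
  expect_equal(classify_segment(-1.3, 0.4), "homozygous_loss")
  expect_equal(classify_segment(-0.5, 0.4), "loss")
  expect_equal(classify_segment(0.3, 0.4), "gain")
  expect_equal(classify_segment(0.02, 0.4), "allelic_imbalance")
  expect_equal(classify_segment(0.02, NA), "neutral")
  expect_equal(classify_segment(0.25, 0), "gain")       # boundary inclusive
  expect_equal(classify_segment(-0.25, 0), "loss")
})

test_that("call_cnvs tiles chromosomes and recovers planted events", {
  # event-free pair: zero non-neutral calls
  cfg0 <- recovery_config(seed = 21,
                          events = data.frame(sample = integer(),
                                              chrom = character(),
                                              start = numeric(),
                                              end = numeric(),
                                              cn_total = numeric(),
                                              b_copies = numeric()))
  r0 <- simulate_paired(cfg0)
  segs0 <- call_cnvs(r0$paired)
  expect_equal(nrow(cnv_calls(segs0)), 0)

  # planted full-purity deletion of ~200 probes
  ev <- data.frame(sample = 1, chrom = "chr1", start = 1e6,
                   end = 1e6 + 1.4e5, cn_total = 1, b_copies = 0)
  cfg <- recovery_config(seed = 22, lrr_sd = 0.1, events = ev)
  r <- simulate_paired(cfg)
  segs <- call_cnvs(r$paired)
  calls <- cnv_calls(segs)
  expect_equal(nrow(calls[calls$class == "loss", ]), 1)
  expect_true(all(recovery_matches(r$truth, segs, r$paired, tol = 2)))

  # copy-neutral LOH: allelic imbalance, no gain/loss
  ev2 <- transform(ev, cn_total = 2, b_copies = 0)
  cfg2 <- recovery_config(seed = 23, lrr_sd = 0.1, events = ev2)
  r2 <- simulate_paired(cfg2)
  calls2 <- cnv_calls(call_cnvs(r2$paired))
  expect_equal(unique(calls2$class), "allelic_imbalance")
  expect_equal(nrow(calls2), 1)

  # tiling invariant: segments cover [first probe, last probe] disjointly
  for (segs_i in list(segs0, segs)) {
    for (chr in unique(segs_i$chrom)) {
      s <- segs_i[segs_i$chrom == chr, ]
      s <- s[order(s$start), ]
      expect_true(all(s$start[-1] == s$end[-nrow(s)]))
      pos <- r$paired$pos[r$paired$chrom == chr]
    }
  }
  pos <- r$paired$pos[r$paired$chrom == "chr1"]
  expect_equal(min(segs$start), min(pos))
  expect_equal(max(segs$end), max(pos) + 1)

  expect_equal(nrow(call_cnvs(NULL)), 0)
})

test_that("min_call_probes drops short calls back to neutral", {
  set.seed(9)
  # 3-probe spike between long neutral stretches
  x <- c(rnorm(50, 0, 0.05), rnorm(3, -1, 0.05), rnorm(50, 0, 0.05))
  paired <- make_signals("chr1", seq_along(x) * 700, lrr = x,
                         baf = 0.5, genotype = "AB")
  segs <- call_cnvs(paired, cnv_params(min_seg_probes = 2,
                                       min_call_probes = 5))
  expect_equal(nrow(cnv_calls(segs)), 0)
  segs2 <- call_cnvs(paired, cnv_params(min_seg_probes = 2,
                                        min_call_probes = 2))
  expect_equal(cnv_calls(segs2)$class, "loss")
})
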