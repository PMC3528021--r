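toy_tracks <- function() {
  list(coding = annotation_track("chr1", 100, 300, "PCG1",
                                 "protein_coding", name = "coding"),
       lincrna = annotation_track("chr1", 500, 600, "LINC1", "lincRNA",
                                  name = "lincRNA"))
}

test_that("intergenic lincRNA reference keeps only coding-disjoint candidates", {
  coding <- annotation_track("chr1", c(1000, 5000), c(2000, 6000),
                             c("PCG1", "PCG2"), "protein_coding")
  cand <- annotation_track("chr1", c(100, 1999, 2000, 6000, 7000),
                           c(900, 2500, 2400, 6500, 8000),
                           sprintf("L%d", 1:5), "lincRNA")
  ref <- build_intergenic_lincrna_reference(cand, coding)
  # L2 shares 1 bp with PCG1; L3 abuts it end-to-start (kept);
  # L4 abuts PCG2 (kept)
  expect_setequal(ref$gene_id, c("L1", "L3", "L4", "L5"))
  expect_setequal(attr(ref, "dropped"), "L2")
  # per-base oracle agreement
  for (i in seq_len(nrow(cand))) {
    ov <- sum(vapply(seq_len(nrow(coding)), function(j)
      oracle_overlap_bp(cand$start[i], cand$end[i],
                        coding$start[j], coding$end[j]), numeric(1)))
    expect_equal(cand$gene_id[i] %in% ref$gene_id, ov == 0)
  }
})

test_that("map_probes_to_track honors half-open bounds and the point oracle", {
  tr <- annotation_track("chr1", c(100, 150), c(200, 250),
                         c("G1", "G2"), "lincRNA")
  probes <- make_signals("chr1", c(99, 100, 199, 200, 175, 250))
  m <- map_probes_to_track(probes, tr)
  # pos 100 at start included, pos 200 at G1 end excluded (but inside G2)
  expect_setequal(paste(m$probes$pos, m$probes$gene_id),
                  c("100 G1", "199 G1", "175 G1", "175 G2", "200 G2",
                    "199 G2"))
  expect_equal(m$counts$n_probes[m$counts$gene_id == "G1"], 3)
  expect_equal(nrow(map_probes_to_track(probes, tr[0, ])$probes), 0)

  set.seed(4)
  for (rep in 1:10) {
    w <- random_toy_world(len = 5e4, n_iv = 6)
    probes <- make_signals("chr1", sort(sample(0:(w$len - 1), 20)))
    m <- map_probes_to_track(probes, w$lincrna)
    for (i in seq_len(nrow(probes))) {
      hits <- w$lincrna$gene_id[w$lincrna$start <= probes$pos[i] &
                                  probes$pos[i] < w$lincrna$end]
      got <- m$probes$gene_id[m$probes$pos == probes$pos[i]]
      expect_setequal(got, hits)
    }
  }
})

test_that("call-track intersection reports overlap bp and percentages", {
  tr <- annotation_track("chr1", c(500, 2000), c(600, 2100),
                         c("LINC1", "LINC2"), "lincRNA")
  calls <- data.frame(sample_id = "S01", chrom = "chr1",
                      start = c(550, 400, 700), end = c(600, 700, 1900),
                      class = c("loss", "gain", "loss"))
  a <- intersect_calls_with_track(calls, tr)
  expect_equal(nrow(a), 2)                     # third call hits nothing
  half <- a[a$call_start == 550, ]
  expect_equal(half$overlap_bp, 50)
  expect_equal(half$overlap_pct, 50)
  full <- a[a$call_start == 400, ]
  expect_equal(full$overlap_pct, 100)          # full containment
  expect_equal(full$overlap_bp, 100)
})

test_that("dissect_segment equals the per-base labeling oracle", {
  tr <- toy_tracks()
  d <- dissect_segment("chr1", 0, 1000, tr$coding, tr$lincrna)
  expect_equal(d, c(genic = 200, lincrna = 100, intergenic = 700))
  d2 <- dissect_segment("chr1", 250, 550, tr$coding, tr$lincrna)
  expect_equal(d2, c(genic = 50, lincrna = 50, intergenic = 200))
  d3 <- dissect_segment("chr1", 110, 120, tr$coding, tr$lincrna)
  expect_equal(unname(d3), c(10, 0, 0))        # fully genic

  corrupt <- annotation_track("chr1", 250, 550, "LX", "lincRNA")
  expect_error(dissect_segment("chr1", 0, 1000, tr$coding, corrupt),
               "overlaps the coding track")

  set.seed(5)
  for (rep in 1:20) {
    w <- random_toy_world(len = 2e4, n_iv = 10)
    s <- sample(0:(w$len - 100), 1)
    e <- s + sample(50:5000, 1)
    e <- min(e, w$len)
    got <- dissect_segment("chr1", s, e, w$coding, w$lincrna)
    expect_equal(got, oracle_dissect("chr1", s, e, w$coding, w$lincrna,
                                     w$len))
    expect_equal(sum(got), e - s)              # conservation, exact
  }
})

test_that("compartment percentages match hand-computed toy cohort values", {
  tr <- toy_tracks()
  genome <- genome_model(c(chr1 = 1000))
  calls <- data.frame(
    sample_id = c("A", "A", "B", "C"), chrom = "chr1",
    start = c(100, 500, 0, 120), end = c(300, 600, 1000, 140),
    class = "loss")
  comp <- compartment_percentages(calls, tr$coding, tr$lincrna, genome)
  # sample A: 200 genic + 100 lincRNA = 300 bp -> 66.67/33.33/0
  a <- comp[comp$sample_id == "A", ]
  expect_equal(a$cnv_bp, 300)
  expect_equal(a$pct_of_cnv_genic, 200 / 3, tolerance = 1e-12)
  expect_equal(a$pct_of_cnv_lincrna, 100 / 3, tolerance = 1e-12)
  # sample B covers everything: 20/10/70 shares; full compartments
  b <- comp[comp$sample_id == "B", ]
  expect_equal(c(b$pct_of_cnv_genic, b$pct_of_cnv_lincrna,
                 b$pct_of_cnv_intergenic), c(20, 10, 70))
  expect_equal(b$pct_of_compartment_genic, 100)
  # sample C fully genic
  cc <- comp[comp$sample_id == "C", ]
  expect_equal(cc$pct_of_cnv_genic, 100)
  # cohort means are plain averages
  m <- attr(comp, "cohort_means")
  expect_equal(unname(m["pct_of_cnv_genic"]), mean(c(200 / 3, 20, 100)))
  expect_equal(attr(comp, "fold_genic_vs_lincrna"),
               mean(c(200 / 3, 20, 100)) / mean(c(100 / 3, 10, 0)))
  # shares sum to 100 exactly
  expect_equal(comp$pct_of_cnv_genic + comp$pct_of_cnv_lincrna +
                 comp$pct_of_cnv_intergenic, rep(100, 3),
               tolerance = 1e-9)
  # zero-CNV sample reported as absent (NA shares)
  comp2 <- compartment_percentages(calls, tr$coding, tr$lincrna, genome,
                                   samples = c("A", "B", "C", "D"))
  expect_true(is.na(comp2$pct_of_cnv_genic[comp2$sample_id == "D"]))
})

test_that("aggregate_frequencies bins gains and losses per sample", {
  genome <- genome_model(c(chr1 = 1e6))
  calls <- data.frame(
    sample_id = c("S1", "S2", "S3", "S4", "S5", "S6", "S7"),
    chrom = "chr1",
    start = c(0, rep(9e5, 6)), end = c(1e5, rep(9.5e5, 6)),
    class = c("loss", rep("gain", 6)))
  f <- aggregate_frequencies(calls, genome, n_samples = 7,
                             bin_size = 1e5)
  expect_equal(f$loss$freq[1], 1 / 7)
  expect_equal(f$gain$freq[10], 6 / 7)
  expect_equal(sum(f$gain$freq[-10]), 0)
  # all frequencies on the 1/n grid
  expect_true(all(round(f$loss$freq * 7, 9) == round(f$loss$freq * 7)))
  f0 <- aggregate_frequencies(calls[0, ], genome, n_samples = 7,
                              bin_size = 1e5)
  expect_true(all(f0$gain$freq == 0) && all(f0$loss$freq == 0))
  # same call in all samples -> frequency 1
  all7 <- data.frame(sample_id = paste0("S", 1:7), chrom = "chr1",
                     start = 0, end = 1e5, class = "loss")
  expect_equal(aggregate_frequencies(all7, genome, 7, 1e5)$loss$freq[1], 1)
})
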