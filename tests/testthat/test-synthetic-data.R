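test_that("simulate_genome places disjoint tracks and honors edge cases", {
  cfg <- sim_config(seed = 11, chrom_lengths = c(chr1 = 1e7),
                    n_coding = 10, n_lincrna = 5)
  w <- simulate_genome(cfg)
  combined <- rbind(as.data.frame(w$coding)[, 1:4],
                    as.data.frame(w$lincrna)[, 1:4])
  expect_equal(nrow(combined), 15)
  expect_true(oracle_all_disjoint(combined))
  expect_true(all(w$coding$end <= 1e7) && all(w$lincrna$end <= 1e7))

  # empty lincRNA case
  w0 <- simulate_genome(sim_config(seed = 11, n_lincrna = 0))
  expect_equal(nrow(w0$lincrna), 0)
  expect_gt(nrow(w0$coding), 0)

  # determinism under seed
  w2 <- simulate_genome(cfg)
  expect_identical(w, w2)

  # impossible fit fails explicitly
  expect_error(
    simulate_genome(sim_config(seed = 1, chrom_lengths = c(chr1 = 1e4),
                               n_coding = 50, n_lincrna = 0,
                               coding_size = c(5e3, 9e3))),
    "could not fit")
})

test_that("plant_events derives classes from copy states", {
  expect_equal(event_class_from_state(0, 0), "homozygous_loss")
  expect_equal(event_class_from_state(2, 0), "allelic_imbalance")
  expect_equal(event_class_from_state(2, 2), "allelic_imbalance")
  expect_true(is.na(event_class_from_state(2, 1)))  # normal het state

  g <- genome_model(c(chr1 = 1e6))
  mk <- function(ev) sim_config(seed = 1, n_pairs = 1,
                                chrom_lengths = c(chr1 = 1e6), events = ev)
  ev <- data.frame(sample = 1, chrom = "chr1",
                   start = c(100, 5000, 9000), end = c(400, 6000, 9500),
                   cn_total = c(2, 0, 2), b_copies = c(1, 0, 0))
  truth <- plant_events(mk(ev), g)
  # the CN=2/b=1 spec row is the normal state: no event emitted
  expect_equal(nrow(truth), 2)
  expect_setequal(truth$class, c("homozygous_loss", "allelic_imbalance"))

  bad <- data.frame(sample = 1, chrom = "chr1", start = c(100, 300),
                    end = c(500, 700), cn_total = c(1, 3),
                    b_copies = c(0, 2))
  expect_error(plant_events(mk(bad), g), "overlapping")
  out_of_bounds <- data.frame(sample = 1, chrom = "chr1", start = 100,
                              end = 2e6, cn_total = 1, b_copies = 0)
  expect_error(mk(out_of_bounds), "bounds")
})

test_that("probe signals follow the purity dilution model exactly at zero noise", {
  ev <- data.frame(sample = 1, chrom = "chr1", start = 2e5, end = 4e5,
                   cn_total = 1, b_copies = 0)
  base <- list(n_pairs = 1, chrom_lengths = c(chr1 = 1e6), n_coding = 8,
               n_lincrna = 4, lrr_sd = 0,
               baf_sd = 0, gc_amplitude = 0, replicates = 1L, nc_rate = 0,
               events = ev)
  run_one <- function(purity) {
    cfg <- do.call(sim_config, c(base, list(seed = 3, purity = purity)))
    w <- simulate_genome(cfg)
    truth <- plant_events(cfg, w$genome)
    sig <- simulate_probe_signals(w$genome, truth, cfg)
    s <- sig$samples$S01
    paired <- s$tumor[[1]]$lrr - s$normal[[1]]$lrr
    in_ev <- s$tumor[[1]]$pos >= 2e5 & s$tumor[[1]]$pos < 4e5
    list(arr = s$tumor[[1]], paired = paired, in_ev = in_ev)
  }
  r1 <- run_one(1)
  expect_equal(mean(r1$paired[r1$in_ev]), -1, tolerance = 1e-9)
  expect_equal(mean(r1$paired[!r1$in_ev]), 0, tolerance = 1e-9)
  r05 <- run_one(0.5)
  expect_equal(mean(r05$paired[r05$in_ev]), log2(0.75), tolerance = 1e-9)

  # copy-neutral LOH: het probes driven to BAF 0 at full purity
  ev2 <- transform(ev, cn_total = 2, b_copies = 0)
  cfg2 <- do.call(sim_config, c(base[names(base) != "events"],
                                list(seed = 3, purity = 1, events = ev2)))
  w2 <- simulate_genome(cfg2)
  truth2 <- plant_events(cfg2, w2$genome)
  sig2 <- simulate_probe_signals(w2$genome, truth2, cfg2)
  arr2 <- sig2$samples$S01$tumor[[1]]
  in_ev2 <- arr2$pos >= 2e5 & arr2$pos < 4e5
  het <- arr2$genotype == "AB"
  expect_true(all(arr2$baf[in_ev2 & het] == 0))
  expect_true(all(arr2$baf[!in_ev2 & het] == 0.5))
})

test_that("probe signals are deterministic, BAF-bounded, and spacing-shaped", {
  cfg <- sim_config(seed = 42, n_pairs = 2, chrom_lengths = c(chr1 = 2e6),
                    n_coding = 10, n_lincrna = 5, n_events = c(1, 2))
  w <- simulate_genome(cfg)
  truth <- plant_events(cfg, w$genome)
  s1 <- simulate_probe_signals(w$genome, truth, cfg)
  s2 <- simulate_probe_signals(w$genome, truth, cfg)
  expect_identical(s1, s2)
  for (arr in c(s1$samples$S01$tumor, s1$samples$S01$normal)) {
    expect_true(all(arr$baf >= 0 & arr$baf <= 1))
    expect_true(all(is.finite(arr$lrr)))
  }
  gaps <- diff(s1$manifest$pos)
  expect_equal(mean(gaps[gaps > 0]), cfg$spacing, tolerance = 0.1)
})

test_that("qPCR simulation follows the efficiency model", {
  # E = 1: one cycle per doubling, log2(10) cycles per decade
  with_seed <- function(s, code) { set.seed(s); code }
  set.seed(1)
  std <- simulate_dilution_standard(c(64, 32, 10, 1), efficiency = 1,
                                    noise_sd = 0, replicates = 1)
  ct <- std$ct[match(c(64, 32, 10, 1), std$quantity)]
  expect_equal(ct[2] - ct[1], 1, tolerance = 1e-9)
  expect_equal(ct[4] - ct[3], log2(10), tolerance = 1e-9)
  expect_error(simulate_dilution_standard(c(1, 0)), "must be > 0")

  # determinism at zero noise and under seed
  cfg <- sim_config(seed = 5, n_pairs = 2, chrom_lengths = c(chr1 = 2e6),
                    n_coding = 10, n_lincrna = 5, n_events = c(1, 2))
  w <- simulate_genome(cfg)
  truth <- annotate_truth_lincrnas(plant_events(cfg, w$genome), w$lincrna)
  q1 <- simulate_qpcr(truth, cfg)
  q2 <- simulate_qpcr(truth, cfg)
  expect_identical(q1, q2)
  expect_setequal(unique(q1$ct$role), c("standard", "target", "reference"))
  # references present for every assayed sample at every level
  refs <- q1$ct[q1$ct$role == "reference", ]
  expect_setequal(unique(refs$assay), c("ALPHA_SAT", "ALB"))
})
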