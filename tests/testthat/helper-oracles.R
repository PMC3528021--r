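# Independent brute-force oracles and small fixture builders.  Every
# oracle here deliberately uses the dumbest possible algorithm (per-base
# labeling, O(n^2) pairwise scans, full 2^n enumeration) so it shares no
# code path with the implementation it checks.

# Label every base of [0, len) as genic / lincrna / intergenic by linear
# scan over the track rows.
oracle_label_bases <- function(len, chrom, coding, lincrna) {
  lab <- rep("intergenic", len)
  paint <- function(track, value) {
    sub <- track[track$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      s <- max(0, sub$start[i]); e <- min(len, sub$end[i])
      if (e > s) lab[(s + 1):e] <<- value
    }
  }
  paint(coding, "genic")
  paint(lincrna, "lincrna")
  lab
}

# Per-base dissection of one call.
oracle_dissect <- function(chrom, start, end, coding, lincrna, len) {
  lab <- oracle_label_bases(len, chrom, coding, lincrna)[(start + 1):end]
  c(genic = sum(lab == "genic"), lincrna = sum(lab == "lincrna"),
    intergenic = sum(lab == "intergenic"))
}

# Per-base overlap of two half-open intervals.
oracle_overlap_bp <- function(s1, e1, s2, e2) {
  sum((seq(s1, e1 - 1)) >= s2 & (seq(s1, e1 - 1)) < e2)
}

# O(n^2) pairwise disjointness check.
oracle_all_disjoint <- function(track) {
  n <- nrow(track)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && track$chrom[i] == track$chrom[j] &&
          track$start[i] < track$end[j] && track$end[i] > track$start[j]) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Exact Wilcoxon signed-rank p-value by enumerating all 2^n sign
# assignments.
oracle_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    pos <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    sum(r[pos])
  }, numeric(1))
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  list(statistic = w_obs, p.value = min(1, 2 * min(p_le, p_ge)))
}

# Exhaustive best-split scan with the pooled-variance t statistic.
oracle_best_split <- function(x, m) {
  n <- length(x)
  best <- list(index = NA_integer_, t = -Inf)
  for (i in m:(n - m)) {
    l <- x[1:i]; r <- x[(i + 1):n]
    sp2 <- (sum((l - mean(l))^2) + sum((r - mean(r))^2)) / (n - 2)
    se <- sqrt(sp2 * (1 / length(l) + 1 / length(r)))
    tt <- if (se > 0) abs(mean(l) - mean(r)) / se else
      if (mean(l) != mean(r)) Inf else 0
    if (tt > best$t) best <- list(index = i, t = tt)
  }
  best
}

# Random toy world (genome + disjoint tracks) for oracle-equivalence
# tests: one chromosome of at most `len` bp, up to n_iv intervals split
# between the two tracks.
random_toy_world <- function(len = 1e5, n_iv = 20) {
  n <- sample(2:n_iv, 1)
  starts <- sort(sample(0:(len - 2), n))
  ends <- pmin(starts + sample(1:(len %/% 10), n, replace = TRUE), len)
  # enforce disjointness by clipping at the next start
  ends[-n] <- pmin(ends[-n], starts[-1])
  ok <- ends > starts
  starts <- starts[ok]; ends <- ends[ok]; n <- length(starts)
  is_cod <- runif(n) < 0.5
  list(
    len = len,
    coding = annotation_track(rep("chr1", sum(is_cod)), starts[is_cod],
                              ends[is_cod],
                              sprintf("PCG%03d", seq_len(sum(is_cod))),
                              "protein_coding", name = "coding"),
    lincrna = annotation_track(rep("chr1", sum(!is_cod)), starts[!is_cod],
                               ends[!is_cod],
                               sprintf("LINC%03d", seq_len(sum(!is_cod))),
                               "lincRNA", name = "lincRNA"))
}

# Minimal probe-signal data.frame builder.
make_signals <- function(chrom, pos, lrr = 0, baf = 0.5, genotype = "AB",
                         gc = 0.5, probe_id = NULL) {
  n <- length(pos)
  data.frame(probe_id = probe_id %||% sprintf("P%04d", seq_len(n)),
             chrom = rep_len(chrom, n), pos = pos,
             lrr = rep_len(lrr, n), baf = rep_len(baf, n),
             genotype = rep_len(genotype, n), gc = rep_len(gc, n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Compact simulation world for segmentation-recovery tests: one 3 Mb
# chromosome, explicit per-class events, single replicate.
recovery_config <- function(seed, purity = 1, lrr_sd = 0.15,
                            events = NULL) {
  if (is.null(events)) {
    # one event per class plus a minimal 20-probe loss, sizes spanning
    # roughly 20-500 probes at 700 bp spacing
    events <- data.frame(
      sample = 1L, chrom = "chr1",
      start = c(2e5, 8e5, 14e5, 20e5, 26e5),
      end = c(2e5 + 70e3, 8e5 + 2.1e5, 14e5 + 3.5e4, 20e5 + 2.8e5,
              26e5 + 1.4e4),
      cn_total = c(3, 1, 0, 2, 1), b_copies = c(2, 0, 0, 0, 0))
  }
  sim_config(seed = seed, n_pairs = 1,
             chrom_lengths = c(chr1 = 3e6), n_coding = 10, n_lincrna = 5,
             spacing = 700, purity = purity, lrr_sd = lrr_sd,
             replicates = 1L, events = events)
}

# Simulate one pair and return list(paired, truth, pos) ready for
# call_cnvs, mirroring the pipeline stages in memory.
simulate_paired <- function(config) {
  world <- simulate_genome(config)
  truth <- plant_events(config, world$genome)
  sig <- simulate_probe_signals(world$genome, truth, config)
  s <- sig$samples[[1]]
  tumor <- combine_replicates(s$tumor)
  normal <- combine_replicates(s$normal)
  normal <- filter_probes(normal)
  tumor <- filter_probes(tumor, drop_nc = FALSE)
  tumor <- tumor[tumor$probe_id %in% normal$probe_id, ]
  list(paired = pair_adjust(gc_correct(tumor), gc_correct(normal)),
       truth = truth, world = world)
}

# Match planted events against calls: class equal, both breakpoints
# within `tol` probes (indices on the paired probe grid).
recovery_matches <- function(truth, segs, paired, tol = 5) {
  calls <- segs[segs$class != "neutral", , drop = FALSE]
  vapply(seq_len(nrow(truth)), function(i) {
    pos <- paired$pos[paired$chrom == truth$chrom[i]]
    idx_of <- function(s, e) {
      inside <- which(pos >= s & pos < e)
      if (!length(inside)) return(c(NA, NA))
      range(inside)
    }
    ti <- idx_of(truth$start[i], truth$end[i])
    cand <- calls[calls$chrom == truth$chrom[i] &
                    calls$class == truth$class[i] &
                    calls$start < truth$end[i] &
                    calls$end > truth$start[i], , drop = FALSE]
    if (!nrow(cand) || any(is.na(ti))) return(FALSE)
    any(vapply(seq_len(nrow(cand)), function(k) {
      ci <- idx_of(cand$start[k], cand$end[k])
      !any(is.na(ci)) && all(abs(ci - ti) <= tol)
    }, logical(1)))
  }, logical(1))
}
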