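#' Log R ratio from intensities
#'
#' `LRR = log2(R_subject / R_expected)`: the log2 ratio of the observed
#' total probe intensity to the intensity expected for a diploid genome.
#' 0 means two copies; each halving of dosage subtracts one.
#'
#' @param r_subject,r_expected strictly positive total intensities.
#' @return numeric LRR, vectorized.
#' @examples
#' compute_lrr(1, 2)   # one copy lost at full purity: -1
#' @export
compute_lrr <- function(r_subject, r_expected) {
  if (any(r_subject <= 0) || any(r_expected <= 0)) {
    stopf("intensities must be strictly positive")
  }
  log2(r_subject / r_expected)
}

#' B-allele frequency from allele intensities
#'
#' `BAF = B / (A + B)`, the fraction of the signal attributable to the B
#' allele; approximately 0, 0.5 and 1 for diploid AA, AB and BB genotypes.
#'
#' @param a,b non-negative allele intensities with `a + b > 0`.
#' @return numeric BAF in `[0, 1]`, vectorized.
#' @export
compute_baf <- function(a, b) {
  if (any(a < 0) || any(b < 0)) stopf("allele intensities must be >= 0")
  if (any(a + b == 0)) stopf("uncallable probe: A + B = 0")
  b / (a + b)
}

#' Filter probes prior to analysis
#'
#' Drops probes on the Y chromosome and (by default) probes whose genotype
#' call failed (`NC`), mirroring array pre-import filtering in a female
#' cohort.  Probe order is preserved; the operation is idempotent.
#'
#' @param signals probe-signal data.frame with columns `chrom`, `genotype`.
#' @param genome optional [genome_model()] (unused for the predicate but
#'   accepted so callers can pass pipeline context).
#' @param drop_nc drop `NC` genotypes (applied to the normal sample's
#'   calls; tumor genotypes may legitimately be aberrant).
#' @return the retained rows, original order.
#' @export
filter_probes <- function(signals, genome = NULL, drop_nc = TRUE) {
  keep <- !is_chrY(signals$chrom)
  if (drop_nc) keep <- keep & signals$genotype != "NC"
  out <- signals[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine replicate arrays of one sample
#'
#' Per probe, LRR and BAF are arithmetic means across replicates.  The
#' genotype is taken from the first replicate; probes on which replicates
#' disagree are set to `NC` (and will fall to [filter_probes()]).
#'
#' @param replicates list of probe-signal data.frames sharing one probe
#'   set.
#' @return a single combined probe-signal data.frame.
#' @export
combine_replicates <- function(replicates) {
  stopifnot(is.list(replicates), length(replicates) >= 1)
  base <- replicates[[1]]
  if (length(replicates) == 1) return(base)
  for (r in replicates[-1]) {
    if (nrow(r) != nrow(base) || !identical(r$probe_id, base$probe_id)) {
      stopf("replicate arrays must share the probe set")
    }
  }
  out <- base
  out$lrr <- rowMeans(vapply(replicates, function(r) r$lrr,
                             numeric(nrow(base))))
  out$baf <- rowMeans(vapply(replicates, function(r) r$baf,
                             numeric(nrow(base))))
  agree <- Reduce(`&`, lapply(replicates[-1], function(r)
    r$genotype == base$genotype))
  out$genotype <- ifelse(agree, base$genotype, "NC")
  out
}

#' GC-wave correction by linear regression
#'
#' Fits a least-squares line of LRR on the per-probe GC covariate and
#' subtracts the GC-dependent component, `lrr - b * (gc - mean(gc))`,
#' which removes any GC-tracking wave while preserving the grand mean of
#' LRR exactly.  The slope is estimated on dosage-typical probes only
#' (LRR within `trim` robust standard deviations of the median): copy
#' events can cover a sizable fraction of a chromosome and would
#' otherwise leak into the GC coefficient and bias corrected signals in
#' a position-dependent way.  BAF and all other columns are untouched.
#' A constant GC covariate makes the fit singular; the correction is
#' then skipped with a warning.
#'
#' @param signals probe-signal data.frame with columns `lrr` and `gc`.
#' @param trim robust z-score beyond which probes are excluded from the
#'   slope estimate (they are still corrected).
#' @return corrected data.frame.
#' @export
gc_correct <- function(signals, trim = 3) {
  if (is.null(signals$gc)) stopf("no GC covariate available")
  if (nrow(signals) < 3) stopf("need >= 3 probes for the GC fit")
  if (stats::var(signals$gc) == 0) {
    warning("GC covariate is constant; correction skipped", call. = FALSE)
    return(signals)
  }
  lrr <- signals$lrr
  gc <- signals$gc
  s <- stats::mad(lrr)
  keep <- if (s > 0) abs(lrr - stats::median(lrr)) <= trim * s else
    rep(TRUE, length(lrr))
  if (sum(keep) < 3 || stats::var(gc[keep]) == 0) keep <- rep(TRUE, length(lrr))
  b <- stats::cov(gc[keep], lrr[keep]) / stats::var(gc[keep])
  signals$lrr <- lrr - b * (gc - mean(gc))
  signals
}

#' Matched-pair adjustment
#'
#' Subtracts the normal sample's LRR from the tumor's per probe, removing
#' germline copy-number structure and shared technical waves; carries the
#' tumor BAF and the normal genotype through.  Both inputs must hold the
#' same probe set; output is sorted by (chromosome, position).
#'
#' @param tumor,normal probe-signal data.frames after filtering.
#' @return a paired-signal data.frame with columns `probe_id`, `chrom`,
#'   `pos`, `lrr` (tumor - normal), `baf` (tumor), `genotype` (normal).
#' @export
pair_adjust <- function(tumor, normal) {
  if (nrow(tumor) != nrow(normal) ||
      !setequal(tumor$probe_id, normal$probe_id)) {
    stopf("tumor and normal probe sets differ (%d vs %d probes)",
          nrow(tumor), nrow(normal))
  }
  t_ord <- tumor[order(tumor$chrom, tumor$pos, tumor$probe_id), ]
  n_ord <- normal[match(t_ord$probe_id, normal$probe_id), ]
  out <- data.frame(probe_id = t_ord$probe_id, chrom = t_ord$chrom,
                    pos = t_ord$pos, lrr = t_ord$lrr - n_ord$lrr,
                    baf = t_ord$baf, genotype = n_ord$genotype,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Robust per-sample noise quality score
#'
#' Median absolute difference of consecutive-probe LRRs within each
#' chromosome, divided by sqrt(2): a robust estimate of per-probe noise sd
#' that is insensitive to step changes from real copy-number events.
#' Lower is better; values above `warn_above` (conventional QC gate 0.02
#' for high-quality arrays, configurable) trigger a warning only.
#'
#' @param signals probe-signal data.frame sorted by chromosome/position.
#' @param warn_above QC warning threshold, `NULL` to disable.
#' @return the quality score (numeric scalar).
#' @export
quality_score <- function(signals, warn_above = NULL) {
  if (nrow(signals) < 2) stopf("need >= 2 probes for a quality score")
  s <- signals[order(signals$chrom, signals$pos), ]
  diffs <- unlist(lapply(split(s$lrr, s$chrom), function(x)
    if (length(x) >= 2) abs(diff(x)) else numeric(0)), use.names = FALSE)
  if (!length(diffs)) stopf("no consecutive probe pairs within a chromosome")
  score <- median(diffs) / sqrt(2)
  if (!is.null(warn_above) && score > warn_above) {
    warning(sprintf("quality score %.4f exceeds %.4f (lower is better)",
                    score, warn_above), call. = FALSE)
  }
  score
}
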