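#' Fit a qPCR standard curve
#'
#' Least-squares regression of Ct on log10(input quantity) over a serial
#' dilution.  The amplification efficiency follows from the slope as
#' `E = 10^(-1/slope) - 1`; a perfectly efficient assay has slope
#' -1/log10(2) = -3.3219 (one cycle per doubling).
#'
#' @param quantity input quantities (ng), >= 4 distinct positive values.
#' @param ct measured Ct per well (same length as `quantity`).
#' @return list of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `n`.
#' @export
fit_standard_curve <- function(quantity, ct) {
  if (length(quantity) != length(ct)) stopf("quantity/ct length mismatch")
  if (any(quantity <= 0)) stopf("quantities must be > 0")
  if (length(unique(quantity)) < 4) {
    stopf("need >= 4 distinct dilution points")
  }
  fit <- linear_fit(log10(quantity), ct)
  if (fit$slope == 0) stopf("flat standard curve; cannot quantify")
  structure(list(slope = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared,
                 efficiency = 10^(-1 / fit$slope) - 1, n = fit$n),
            class = "standard_curve")
}

#' Quantify a Ct value against a standard curve
#'
#' Inverts the curve: `quantity = 10^((Ct - intercept) / slope)`.
#'
#' @param ct Ct value(s).
#' @param curve a [fit_standard_curve()] result.
#' @return quantity in the curve's input units.
#' @export
quantify <- function(ct, curve) {
  if (!inherits(curve, "standard_curve")) stopf("not a standard curve")
  if (curve$slope == 0) stopf("zero slope; cannot quantify")
  10^((ct - curve$intercept) / curve$slope)
}

#' Predicted Ct for a quantity (inverse of [quantify()])
#'
#' @param quantity input quantity (> 0).
#' @param curve a [fit_standard_curve()] result.
#' @return predicted Ct.
#' @export
predict_ct <- function(quantity, curve) {
  if (any(quantity <= 0)) stopf("quantity must be > 0")
  curve$intercept + curve$slope * log10(quantity)
}

#' Tumor/normal copy-number ratio with dual-reference normalization
#'
#' For each reference r, `ratio_r = (target_T / ref_rT) / (target_N /
#' ref_rN)` per replicate measurement (e.g. the two gDNA input levels);
#' the mean over references and replicates is the reported copy ratio.
#' Classification uses a deviation-from-unity cutoff (default 0.2): loss
#' below `1 - cutoff`, gain above `1 + cutoff` — so a clonal heterozygous
#' loss (expected ratio 0.5) is called.
#'
#' @param target_tumor,target_normal quantified target amounts per
#'   replicate measurement.
#' @param refs_tumor,refs_normal named lists (one entry per reference,
#'   e.g. alpha-satellite and albumin) of quantified amounts, each the
#'   same length as the target vectors.
#' @param cutoff deviation-from-unity threshold.
#' @return list with `ratio` (mean), `per_reference` (named means),
#'   `references_concur` (do all per-reference classes agree), `class` in
#'   loss/normal/gain.
#' @export
copy_ratio <- function(target_tumor, target_normal,
                       refs_tumor, refs_normal, cutoff = 0.2) {
  if (!identical(sort(names(refs_tumor)), sort(names(refs_normal)))) {
    stopf("tumor and normal reference sets differ")
  }
  check_pos <- function(x) if (any(unlist(x) <= 0))
    stopf("quantities must be > 0")
  check_pos(target_tumor); check_pos(target_normal)
  check_pos(refs_tumor); check_pos(refs_normal)
  per_ref <- vapply(names(refs_tumor), function(r) {
    mean((target_tumor / refs_tumor[[r]]) /
           (target_normal / refs_normal[[r]]))
  }, numeric(1))
  classify <- function(x) {
    if (x < 1 - cutoff) "loss" else if (x > 1 + cutoff) "gain" else "normal"
  }
  ratio <- mean(per_ref)
  list(ratio = ratio, per_reference = per_ref,
       references_concur = length(unique(vapply(per_ref, classify,
                                                character(1)))) == 1,
       class = classify(ratio))
}

#' Relative quantity by the 2^-ddCt method
#'
#' `2^-((Ct_target_T - Ct_ref_T) - (Ct_target_N - Ct_ref_N))`: the
#' classical comparator assuming 100% efficiency for both assays.
#'
#' @param ct_target_tumor,ct_ref_tumor,ct_target_normal,ct_ref_normal
#'   finite Ct values (means over replicate wells).
#' @return relative quantity (1 = no change, 0.5 = heterozygous loss).
#' @export
ddct_ratio <- function(ct_target_tumor, ct_ref_tumor,
                       ct_target_normal, ct_ref_normal) {
  ddct <- (ct_target_tumor - ct_ref_tumor) -
    (ct_target_normal - ct_ref_normal)
  if (any(!is.finite(ddct))) stopf("Ct values must be finite")
  2^(-ddct)
}

#' Analyze a simulated or measured qPCR Ct table
#'
#' Fits a standard curve per assay from the `standard` rows, quantifies
#' every unknown well, averages replicate wells within (sample, assay,
#' tissue, input level), and computes the dual-reference tumor/normal
#' [copy_ratio()] per (sample, target) across input levels, alongside the
#' [ddct_ratio()] comparator.
#'
#' @param ct_table data.frame as produced by [simulate_qpcr()].
#' @param references names of the reference assays.
#' @param cutoff deviation-from-unity loss/gain cutoff.
#' @return data.frame: one row per (sample, target assay) with `ratio`,
#'   `class`, `ddct`, per-reference means and the standard-curve
#'   R-squared of the target assay.
#' @export
analyze_qpcr <- function(ct_table, references = c("ALPHA_SAT", "ALB"),
                         cutoff = 0.2) {
  std <- ct_table[ct_table$role == "standard", ]
  curves <- lapply(split(std, std$assay), function(s)
    fit_standard_curve(s$input_ng, s$ct))
  unk <- ct_table[ct_table$role != "standard", ]
  # mean Ct per (sample, assay, tissue, level), then quantity via curve
  key <- interaction(unk$sample, unk$assay, unk$tissue, unk$input_ng,
                     drop = TRUE)
  agg <- do.call(rbind, lapply(split(unk, key), function(g) {
    data.frame(sample = g$sample[1], assay = g$assay[1],
               tissue = g$tissue[1], input_ng = g$input_ng[1],
               ct = mean(g$ct), stringsAsFactors = FALSE)
  }))
  agg$quantity <- vapply(seq_len(nrow(agg)), function(i)
    quantify(agg$ct[i], curves[[agg$assay[i]]]), numeric(1))
  targets <- unique(agg$assay[!(agg$assay %in% references)])
  rows <- list()
  for (smp in unique(agg$sample)) {
    sub <- agg[agg$sample == smp, ]
    get <- function(assay, tissue) {
      x <- sub[sub$assay == assay & sub$tissue == tissue, ]
      x <- x[order(x$input_ng), ]
      list(q = x$quantity, ct = x$ct)
    }
    ref_t <- lapply(references, function(r) get(r, "tumor")$q)
    ref_n <- lapply(references, function(r) get(r, "normal")$q)
    names(ref_t) <- names(ref_n) <- references
    for (a in intersect(targets, sub$assay)) {
      tt <- get(a, "tumor"); tn <- get(a, "normal")
      if (!length(tt$q) || !length(tn$q)) next
      cr <- copy_ratio(tt$q, tn$q, ref_t, ref_n, cutoff = cutoff)
      r1t <- get(references[1], "tumor"); r1n <- get(references[1], "normal")
      dd <- mean(ddct_ratio(tt$ct, r1t$ct, tn$ct, r1n$ct))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = smp, assay = a, ratio = cr$ratio, class = cr$class,
        ddct = dd,
        ratio_ref1 = unname(cr$per_reference[1]),
        ratio_ref2 = unname(cr$per_reference[2]),
        references_concur = cr$references_concur,
        curve_r_squared = curves[[a]]$r_squared,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(), assay = character(),
               ratio = numeric(), class = character(), ddct = numeric(),
               ratio_ref1 = numeric(), ratio_ref2 = numeric(),
               references_concur = logical(),
               curve_r_squared = numeric())
  rownames(out) <- NULL
  out
}
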