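#' Build the intergenic-only lincRNA reference
#'
#' Retains candidate lincRNA genes with zero base pairs of overlap with
#' any protein-coding interval; the rest are dropped (a "lincRNA" that
#' touches a coding gene is not intergenic).  Intervals that merely abut
#' end-to-start share no base and are retained (half-open convention).
#'
#' @param candidates candidate lincRNA [annotation_track()].
#' @param coding protein-coding [annotation_track()].
#' @return the retained track; the dropped gene ids are available in
#'   attribute `dropped`.
#' @export
build_intergenic_lincrna_reference <- function(candidates, coding) {
  if (nrow(candidates) == 0) return(candidates)
  keep <- rep(TRUE, nrow(candidates))
  for (chr in unique(candidates$chrom)) {
    idx <- which(candidates$chrom == chr)
    q <- as_iranges0(candidates$start[idx], candidates$end[idx])
    s <- track_iranges(coding, chr)
    if (length(s)) {
      keep[idx] <- IRanges::countOverlaps(q, s) == 0
    }
  }
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "track_name") <- attr(candidates, "track_name")
  attr(out, "dropped") <- candidates$gene_id[!keep]
  class(out) <- class(candidates)
  out
}

#' Map probes onto an annotation track
#'
#' Returns the probes whose position falls inside any interval of the
#' track (`start <= pos < end`), with one output row per (probe, gene)
#' assignment — a probe inside two overlapping genes is counted for both —
#' plus per-gene probe counts.
#'
#' @param probes data.frame with columns `probe_id`, `chrom`, `pos`.
#' @param track an [annotation_track()].
#' @return list with `probes` (the assigned subset, extra column
#'   `gene_id`) and `counts` (data.frame `gene_id`, `n_probes`).
#' @export
map_probes_to_track <- function(probes, track) {
  rows <- list()
  for (chr in unique(probes$chrom)) {
    pi <- which(probes$chrom == chr)
    ti <- which(track$chrom == chr)
    if (!length(ti) || !length(pi)) next
    q <- as_iranges0(probes$pos[pi], probes$pos[pi] + 1)
    s <- as_iranges0(track$start[ti], track$end[ti])
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov)) {
      hit <- probes[pi[S4Vectors::queryHits(ov)], , drop = FALSE]
      hit$gene_id <- track$gene_id[ti[S4Vectors::subjectHits(ov)]]
      rows[[length(rows) + 1L]] <- hit
    }
  }
  assigned <- if (length(rows)) do.call(rbind, rows) else
    cbind(probes[0, , drop = FALSE], gene_id = character())
  assigned <- assigned[order(assigned$chrom, assigned$pos,
                             assigned$gene_id), , drop = FALSE]
  rownames(assigned) <- NULL
  counts <- if (nrow(assigned)) {
    as.data.frame(table(gene_id = assigned$gene_id),
                  responseName = "n_probes", stringsAsFactors = FALSE)
  } else data.frame(gene_id = character(), n_probes = integer())
  list(probes = assigned, counts = counts)
}

#' Associate CNV calls with lincRNA genes
#'
#' One association per (lincRNA, overlapping call): the overlap length in
#' bp and its percentage of the gene's footprint.  Genes untouched by any
#' call are absent.
#'
#' @param calls non-neutral call data.frame (`chrom`, `start`, `end`,
#'   `class`, optionally `sample_id`).
#' @param track the lincRNA [annotation_track()].
#' @return data.frame with one row per association: gene id, call
#'   coordinates, class, `overlap_bp`, `overlap_pct`.
#' @export
intersect_calls_with_track <- function(calls, track) {
  empty <- data.frame(gene_id = character(), sample_id = character(),
                      chrom = character(), call_start = numeric(),
                      call_end = numeric(), class = character(),
                      gene_start = numeric(), gene_end = numeric(),
                      overlap_bp = numeric(), overlap_pct = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0 || nrow(track) == 0) return(empty)
  sample_id <- calls$sample_id %||% rep(NA_character_, nrow(calls))
  rows <- list()
  for (chr in unique(calls$chrom)) {
    ci <- which(calls$chrom == chr)
    ti <- which(track$chrom == chr)
    if (!length(ti)) next
    for (i in ci) {
      ov_start <- pmax(calls$start[i], track$start[ti])
      ov_end <- pmin(calls$end[i], track$end[ti])
      hit <- which(ov_end > ov_start)
      for (j in hit) {
        tj <- ti[j]
        glen <- track$end[tj] - track$start[tj]
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = track$gene_id[tj], sample_id = sample_id[i],
          chrom = chr, call_start = calls$start[i],
          call_end = calls$end[i], class = calls$class[i],
          gene_start = track$start[tj], gene_end = track$end[tj],
          overlap_bp = ov_end[j] - ov_start[j],
          overlap_pct = 100 * (ov_end[j] - ov_start[j]) / glen,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  out
}

#' Dissect one aberration into genomic compartments
#'
#' Splits a call's base pairs into genic (merged union of coding
#' intervals), lincRNA, and non-lincRNA-intergenic portions.  Because the
#' lincRNA reference is intergenic by construction, the three tallies are
#' disjoint and sum exactly to the call length; overlapping inputs are a
#' corrupt reference and raise an error.
#'
#' @param chrom,start,end call coordinates (0-based half-open).
#' @param coding,lincrna annotation tracks.
#' @return named numeric vector `c(genic =, lincrna =, intergenic =)`.
#' @export
dissect_segment <- function(chrom, start, end, coding, lincrna) {
  if (end <= start) stopf("call needs start < end")
  call_r <- as_iranges0(start, end)
  cod <- IRanges::reduce(track_iranges(coding, chrom))
  lnc <- IRanges::reduce(track_iranges(lincrna, chrom))
  if (length(cod) && length(lnc) &&
      sum(IRanges::countOverlaps(lnc, cod)) > 0) {
    stopf("lincRNA track overlaps the coding track on %s; rebuild the reference",
          chrom)
  }
  ov_bp <- function(subj) {
    if (!length(subj)) return(0)
    sum(IRanges::width(IRanges::intersect(call_r, subj)))
  }
  genic <- ov_bp(cod)
  linc <- ov_bp(lnc)
  c(genic = genic, lincrna = linc,
    intergenic = (end - start) - genic - linc)
}

#' Per-sample compartment summary and cohort means
#'
#' For every sample: (i) the share of total called CNV base pairs falling
#' in the genic, lincRNA and non-lincRNA-intergenic compartments (sums to
#' 100%), and (ii) the fraction of each compartment's genome-wide total
#' affected by CNV.  The genome-wide compartment totals exclude chrY
#' (female genome).  Cohort means and the genic/lincRNA fold ratio of the
#' mean CNV shares are attached as attributes.
#'
#' @param calls non-neutral calls with a `sample_id` column.
#' @param coding,lincrna annotation tracks.
#' @param genome a [genome_model()].
#' @param samples optional character vector fixing the sample universe
#'   (samples with zero CNV bp get `NA` shares).
#' @return data.frame (one row per sample) with bp tallies, `pct_of_cnv_*`
#'   shares and `pct_of_compartment_*` affected fractions; attributes
#'   `cohort_means` and `fold_genic_vs_lincrna`.
#' @export
compartment_percentages <- function(calls, coding, lincrna, genome,
                                    samples = NULL) {
  samples <- samples %||% sort(unique(calls$sample_id))
  totals <- c(genic = track_footprint(coding),
              lincrna = track_footprint(lincrna))
  totals["intergenic"] <- genome_length(genome) - sum(totals)
  rows <- lapply(samples, function(s) {
    cs <- calls[calls$sample_id == s, , drop = FALSE]
    bp <- c(genic = 0, lincrna = 0, intergenic = 0)
    for (i in seq_len(nrow(cs))) {
      bp <- bp + dissect_segment(cs$chrom[i], cs$start[i], cs$end[i],
                                 coding, lincrna)
    }
    tot <- sum(bp)
    share <- if (tot > 0) 100 * bp / tot else rep(NA_real_, 3)
    data.frame(sample_id = s, cnv_bp = tot,
               genic_bp = bp[["genic"]], lincrna_bp = bp[["lincrna"]],
               intergenic_bp = bp[["intergenic"]],
               pct_of_cnv_genic = share[[1]],
               pct_of_cnv_lincrna = share[[2]],
               pct_of_cnv_intergenic = share[[3]],
               pct_of_compartment_genic = 100 * bp[["genic"]] / totals[["genic"]],
               pct_of_compartment_lincrna = 100 * bp[["lincrna"]] / totals[["lincrna"]],
               pct_of_compartment_intergenic = 100 * bp[["intergenic"]] / totals[["intergenic"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  num <- out[, setdiff(names(out), "sample_id")]
  attr(out, "cohort_means") <- colMeans(num, na.rm = TRUE)
  mg <- mean(out$pct_of_cnv_genic, na.rm = TRUE)
  ml <- mean(out$pct_of_cnv_lincrna, na.rm = TRUE)
  attr(out, "fold_genic_vs_lincrna") <-
    if (is.finite(ml) && ml > 0) mg / ml else NA_real_
  attr(out, "compartment_totals") <- totals
  out
}

#' Aggregate cross-sample gain/loss frequencies into genomic bins
#'
#' Partitions each chromosome into fixed-size bins and reports, per bin,
#' the fraction of samples with at least one base pair of gain overlap and
#' likewise for loss (homozygous losses count as losses).  The output is
#' Circos-ready `chrom start end value` data.
#'
#' @param calls non-neutral calls with `sample_id`.
#' @param genome a [genome_model()].
#' @param n_samples cohort size (the frequency denominator).
#' @param bin_size bin width in bp.
#' @return list with data.frames `gain` and `loss`, columns `chrom`,
#'   `start`, `end`, `freq`.
#' @export
aggregate_frequencies <- function(calls, genome, n_samples,
                                  bin_size = 1e6) {
  if (n_samples < 1) stopf("need >= 1 sample")
  class_sets <- list(gain = "gain", loss = c("loss", "homozygous_loss"))
  lens <- genome$lengths[!is_chrY(names(genome$lengths))]
  bins <- do.call(rbind, lapply(names(lens), function(chr) {
    starts <- seq(0, lens[[chr]] - 1, by = bin_size)
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + bin_size, lens[[chr]]))
  }))
  out <- lapply(class_sets, function(classes) {
    sub <- calls[calls$class %in% classes, , drop = FALSE]
    freq <- numeric(nrow(bins))
    for (chr in unique(bins$chrom)) {
      bi <- which(bins$chrom == chr)
      si <- which(sub$chrom == chr)
      if (!length(si)) next
      b <- as_iranges0(bins$start[bi], bins$end[bi])
      hits <- matrix(FALSE, nrow = length(bi),
                     ncol = length(unique(sub$sample_id[si])),
                     dimnames = list(NULL, unique(sub$sample_id[si])))
      for (s in colnames(hits)) {
        ss <- sub[si, ][sub$sample_id[si] == s, , drop = FALSE]
        cr <- as_iranges0(ss$start, ss$end)
        hits[, s] <- IRanges::countOverlaps(b, cr) > 0
      }
      freq[bi] <- rowSums(hits) / n_samples
    }
    cbind(bins, freq = freq)
  })
  out
}
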