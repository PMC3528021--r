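#' Calling parameters
#'
#' Defaults for segmentation and event classification.  The LRR thresholds
#' are on the paired (tumor minus normal) scale: at full purity a single
#' copy loss sits near -1, a single gain near +0.585, a homozygous loss at
#' the array's dynamic-range floor.
#'
#' @param gain_lrr minimum mean paired LRR for a gain call.
#' @param loss_lrr maximum mean paired LRR for a (heterozygous) loss.
#' @param homozygous_lrr maximum mean paired LRR for a homozygous loss.
#' @param baf_dev minimum mean mirrored-BAF deviation for an allelic
#'   imbalance call.
#' @param t_threshold stopping threshold T for the binary-segmentation
#'   t-statistic.
#' @param min_seg_probes minimum probes on each side of an accepted split.
#' @param min_call_probes minimum probes supporting a non-neutral call
#'   (tunable down to 2 for very small events).
#' @return list of class `cnv_params`.
#' @export
cnv_params <- function(gain_lrr = 0.25, loss_lrr = -0.25,
                       homozygous_lrr = -1.1, baf_dev = 0.15,
                       t_threshold = 5, min_seg_probes = 5L,
                       min_call_probes = 5L) {
  if (min_call_probes < 2) stopf("min_call_probes must be >= 2")
  if (min_seg_probes < 2) stopf("min_seg_probes must be >= 2")
  if (homozygous_lrr >= loss_lrr) stopf("homozygous_lrr must be < loss_lrr")
  structure(list(gain_lrr = gain_lrr, loss_lrr = loss_lrr,
                 homozygous_lrr = homozygous_lrr, baf_dev = baf_dev,
                 t_threshold = t_threshold,
                 min_seg_probes = as.integer(min_seg_probes),
                 min_call_probes = as.integer(min_call_probes)),
            class = "cnv_params")
}

#' Mirrored B-allele-frequency deviation
#'
#' Mean of `|BAF - 0.5|` over probes heterozygous in the matched normal:
#' 0 under balanced heterozygosity, approaching 0.5 under complete loss of
#' heterozygosity, where BAFs cluster at 0 and 1.
#'
#' @param baf BAF values at probes with normal genotype AB.
#' @return the deviation, or `NA` when no informative probe is supplied
#'   (the segment is then classified on LRR alone).
#' @export
mirrored_baf_deviation <- function(baf) {
  if (!length(baf)) return(NA_real_)
  mean(abs(baf - 0.5))
}

# Pooled-variance two-sample |t| with a cancellation guard: mean
# differences at floating-point rounding scale are not real contrasts,
# even when the pooled variance underflows to exactly zero.
guarded_t <- function(dm, se, scale) {
  tol <- 1e-8 * (scale + 1e-12)
  tt <- ifelse(se > 0, dm / se, ifelse(dm > tol, Inf, 0))
  tt[dm <= tol] <- 0
  tt
}

# Best binary split of x by the two-sample t statistic (pooled variance).
# Returns list(index = last index of the left part, t = |t|), with the
# leftmost maximizer on ties; index is NA when no admissible split exists.
best_split <- function(x, min_probes) {
  n <- length(x)
  if (n < 2L * min_probes) return(list(index = NA_integer_, t = 0))
  cs <- cumsum(x)
  css <- cumsum(x^2)
  i <- seq.int(min_probes, n - min_probes)   # size of the left part
  nl <- i
  nr <- n - i
  ml <- cs[i] / nl
  mr <- (cs[n] - cs[i]) / nr
  ssl <- css[i] - nl * ml^2
  ssr <- (css[n] - css[i]) - nr * mr^2
  sp2 <- pmax((ssl + ssr) / (n - 2), 0)
  se <- sqrt(sp2 * (1 / nl + 1 / nr))
  tt <- guarded_t(abs(ml - mr), se, max(abs(x)))
  k <- which.max(tt)   # which.max takes the leftmost maximum
  list(index = i[k], t = tt[k])
}

# Best contiguous interval (i, j] of x by the inside-vs-outside pooled
# two-sample t statistic, scanning every window size from min_probes up
# to max_window (capped at n - min_probes).  This is the interval
# statistic of circular-style segmentation: a single split dilutes a
# short interior event across half the chromosome, while the window
# statistic compares the event against everything else and keeps power
# for events of a few dozen probes.  Ties resolve to the smallest
# window, then the leftmost offset.
best_interval <- function(x, min_probes, max_window = 600L) {
  n <- length(x)
  best <- list(i = NA_integer_, j = NA_integer_, t = -Inf)
  if (n < 2L * min_probes) return(best)
  cs <- c(0, cumsum(x))
  css <- c(0, cumsum(x^2))
  tot <- cs[n + 1]
  tot2 <- css[n + 1]
  scale <- max(abs(x))
  for (w in min_probes:min(max_window, n - min_probes)) {
    off <- 0:(n - w)                      # inside = (off, off + w]
    sum_in <- cs[off + w + 1] - cs[off + 1]
    ss2_in <- css[off + w + 1] - css[off + 1]
    mean_in <- sum_in / w
    mean_out <- (tot - sum_in) / (n - w)
    ss_in <- ss2_in - sum_in^2 / w
    ss_out <- (tot2 - ss2_in) - (tot - sum_in)^2 / (n - w)
    sp2 <- pmax((ss_in + ss_out) / (n - 2), 0)
    se <- sqrt(sp2 * (1 / w + 1 / (n - w)))
    tt <- guarded_t(abs(mean_in - mean_out), se, scale)
    # flanks must be empty or hold at least min_probes points
    left <- off
    right <- n - off - w
    tt[!((left == 0 | left >= min_probes) &
           (right == 0 | right >= min_probes))] <- -Inf
    k <- which.max(tt)
    if (tt[k] > best$t) {
      best <- list(i = off[k], j = off[k] + w, t = tt[k])
    }
  }
  best
}

#' Recursive change-point segmentation of an ordered signal
#'
#' At each step the candidate change is either the single split
#' maximizing the pooled two-sample t statistic between left and right
#' means, or the contiguous window (up to `max_window` points) maximizing
#' the inside-vs-outside t statistic — whichever is stronger.  The
#' candidate is accepted when `|t| >= t_threshold` and every resulting
#' piece keeps at least `min_probes` points of support on each side of a
#' cut; the procedure then recurses into the resulting pieces.  The
#' window statistic is what preserves power for short interior events
#' (a few dozen probes on a chromosome of thousands) that a single split
#' statistic dilutes.  A transparent, testable substitute for
#' proprietary SNP-array segmentation engines.
#'
#' @param x numeric signal ordered by genomic position (one chromosome).
#' @param t_threshold stopping threshold T; raising it can only remove
#'   breakpoints.
#' @param min_probes minimum points per side of any accepted cut.
#' @param max_window largest window size scanned by the interval
#'   statistic; longer events are found by the split statistic, which
#'   has ample power at that scale.
#' @return sorted integer breakpoints; breakpoint `k` splits between
#'   positions `k` and `k + 1`.  Degenerate input returns `integer(0)`.
#' @export
segment_signal <- function(x, t_threshold = 5, min_probes = 5L,
                           max_window = 600L) {
  n <- length(x)
  recurse <- function(lo, hi) {
    seg <- x[lo:hi]
    sp <- best_split(seg, min_probes)
    iv <- best_interval(seg, min_probes, max_window)
    t_best <- max(sp$t, iv$t, na.rm = TRUE)
    if (!is.finite(t_best) && t_best < 0) return(integer(0))
    if (t_best < t_threshold) return(integer(0))
    if (!is.na(iv$i) && iv$t > sp$t) {
      cuts <- lo - 1L + c(iv$i, iv$j)          # after seg positions i, j
      cuts <- cuts[cuts >= lo & cuts < hi]
      if (!length(cuts)) return(integer(0))
      bounds <- c(lo - 1L, cuts, hi)
      out <- cuts
      for (k in seq_len(length(bounds) - 1L)) {
        out <- c(out, recurse(bounds[k] + 1L, bounds[k + 1L]))
      }
      sort(out)
    } else {
      cut <- lo + sp$index - 1L
      c(recurse(lo, cut), cut, recurse(cut + 1L, hi))
    }
  }
  if (n < 2L * min_probes) return(integer(0))
  sort(recurse(1L, n))
}

#' Classify one segment into an event class
#'
#' Thresholds are applied with the precedence homozygous loss >
#' gain/loss > allelic imbalance > neutral: a deep deletion is never
#' reported as a mere loss, and a dosage change wins over the allelic
#' signature it also produces.
#'
#' @param mean_lrr mean paired LRR of the segment.
#' @param baf_dev mean mirrored-BAF deviation (`NA` when uninformative).
#' @param params a [cnv_params()].
#' @return one of `"gain"`, `"loss"`, `"homozygous_loss"`,
#'   `"allelic_imbalance"`, `"neutral"`.
#' @export
classify_segment <- function(mean_lrr, baf_dev = NA_real_,
                             params = cnv_params()) {
  if (mean_lrr <= params$homozygous_lrr) return("homozygous_loss")
  if (mean_lrr >= params$gain_lrr) return("gain")
  if (mean_lrr <= params$loss_lrr) return("loss")
  if (!is.na(baf_dev) && baf_dev >= params$baf_dev) {
    return("allelic_imbalance")
  }
  "neutral"
}

# Merge adjacent same-class segments of one chromosome (data.frame rows
# sorted by start); statistics are recombined probe-weighted.
merge_adjacent <- function(seg) {
  if (nrow(seg) <= 1) return(seg)
  grp <- cumsum(c(1L, as.integer(seg$class[-1] != seg$class[-nrow(seg)])))
  out <- do.call(rbind, lapply(split(seg, grp), function(s) {
    data.frame(chrom = s$chrom[1], start = min(s$start), end = max(s$end),
               n_probes = sum(s$n_probes),
               mean_lrr = sum(s$mean_lrr * s$n_probes) / sum(s$n_probes),
               baf_dev = if (all(is.na(s$baf_dev))) NA_real_ else
                 sum(s$baf_dev * s$n_het, na.rm = TRUE) /
                 sum(s$n_het[!is.na(s$baf_dev)]),
               n_het = sum(s$n_het), class = s$class[1],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Call CNV/LOH segments from paired signals
#'
#' Per chromosome, breakpoints from segmenting the paired LRR over all
#' probes and from segmenting the mirrored BAF deviation over probes
#' heterozygous in the normal are unioned; each resulting segment is
#' classified; adjacent same-class segments are merged; non-neutral calls
#' supported by fewer than `min_call_probes` probes are reset to neutral
#' and re-merged.  Segments tile each chromosome from the first to the
#' last probe.
#'
#' @param paired paired-signal data.frame from [pair_adjust()].
#' @param params a [cnv_params()].
#' @return data.frame of segments: `chrom`, `start`, `end` (0-based
#'   half-open, from first/last supporting probe), `n_probes`,
#'   `mean_lrr`, `baf_dev`, `n_het`, `class`, `length`.  Non-neutral rows
#'   are the CNV calls.
#' @export
call_cnvs <- function(paired, params = cnv_params()) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_probes = integer(),
                      mean_lrr = numeric(), baf_dev = numeric(),
                      n_het = integer(), class = character(),
                      length = numeric(), stringsAsFactors = FALSE)
  if (is.null(paired) || nrow(paired) == 0) return(empty)
  paired <- paired[order(paired$chrom, paired$pos), ]
  pieces <- lapply(split(paired, paired$chrom), function(p) {
    n <- nrow(p)
    bp <- segment_signal(p$lrr, params$t_threshold, params$min_seg_probes)
    het <- which(p$genotype == "AB")
    if (length(het) >= 2L * params$min_seg_probes) {
      dev <- abs(p$baf[het] - 0.5)
      bp_h <- segment_signal(dev, params$t_threshold, params$min_seg_probes)
      bp <- union(bp, het[bp_h])   # split after that het probe
    }
    bp <- sort(unique(bp[bp >= 1 & bp < n]))
    bounds <- c(0L, bp, n)
    seg <- do.call(rbind, lapply(seq_len(length(bounds) - 1L), function(k) {
      idx <- (bounds[k] + 1L):bounds[k + 1L]
      hh <- idx[p$genotype[idx] == "AB"]
      dev <- mirrored_baf_deviation(p$baf[hh])
      # interior boundaries sit on the next segment's first probe so the
      # segments tile [first probe, last probe + 1) without gaps
      seg_end <- if (k < length(bounds) - 1L) p$pos[bounds[k + 1L] + 1L] else
        p$pos[n] + 1
      data.frame(chrom = p$chrom[1], start = p$pos[idx[1]],
                 end = seg_end,
                 n_probes = length(idx), mean_lrr = mean(p$lrr[idx]),
                 baf_dev = dev, n_het = length(hh),
                 class = NA_character_, stringsAsFactors = FALSE)
    }))
    seg$class <- vapply(seq_len(nrow(seg)), function(k)
      classify_segment(seg$mean_lrr[k], seg$baf_dev[k], params),
      character(1))
    seg <- merge_adjacent(seg)
    drop <- seg$class != "neutral" & seg$n_probes < params$min_call_probes
    if (any(drop)) {
      seg$class[drop] <- "neutral"
      seg <- merge_adjacent(seg)
    }
    seg
  })
  out <- do.call(rbind, pieces)
  out$length <- out$end - out$start
  rownames(out) <- NULL
  out
}

#' Extract the non-neutral calls from a segment table
#'
#' @param segments output of [call_cnvs()].
#' @return the non-neutral rows.
#' @export
cnv_calls <- function(segments) {
  out <- segments[segments$class != "neutral", , drop = FALSE]
  rownames(out) <- NULL
  out
}
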