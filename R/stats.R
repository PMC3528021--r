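#' Exact two-tailed Wilcoxon signed-rank test
#'
#' Tests symmetry of paired differences about zero.  Zero differences are
#' dropped (Wilcoxon's original rule) and ties receive average ranks.  For
#' `n <= exact_limit` (default 25) the null distribution of
#' `W = sum of ranks of positive differences` is computed exactly over all
#' `2^n` equally likely sign assignments — implemented as a subset-sum
#' convolution over doubled ranks so average ranks stay integral — and the
#' two-tailed p-value is `min(1, 2 * min(P(W <= w), P(W >= w)))`.  Larger
#' samples use the normal approximation with tie correction and a
#' continuity correction.
#'
#' @param differences numeric vector of paired differences.
#' @param exact_limit sample-size crossover from exact enumeration to the
#'   normal approximation.
#' @return list with `statistic` (W), `p.value`, `n` (used), `n_zero`
#'   (dropped), `method`.
#' @export
wilcoxon_signed_rank <- function(differences, exact_limit = 25L) {
  d <- differences[!is.na(differences)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stopf("all differences are zero; test undefined")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    # distribution of 2W over sign assignments via polynomial convolution
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    cnt <- numeric(total + 1L)      # cnt[s + 1] = #subsets with doubled sum s
    cnt[1L] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), cnt[seq_len(total + 1L - rr)])
      cnt <- cnt + shifted
    }
    probs <- cnt / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = w, p.value = p, n = n, n_zero = n_zero, method = method)
}

#' Ordinary least-squares fit with R-squared
#'
#' @param x,y numeric vectors, `n >= 3`, `x` not constant.
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
linear_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stopf("need at least 3 points")
  if (stats::var(x) == 0) stopf("x is constant; no regression possible")
  fit <- stats::lm.fit(cbind(1, x), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r_squared = r2, n = n)
}

#' Fold ratio of two paired proportion vectors
#'
#' Ratio of means (not mean of ratios), reported together with the exact
#' Wilcoxon signed-rank p-value of the paired comparison.
#'
#' @param a,b equal-length numeric vectors (e.g. per-sample genic and
#'   lincRNA CNV shares).
#' @return list with `ratio`, `mean_a`, `mean_b`, `p.value`.
#' @export
fold_ratio <- function(a, b) {
  if (length(a) != length(b)) stopf("vectors must have equal length")
  mb <- mean(b)
  if (!is.finite(mb) || mb <= 0) stopf("denominator mean must be > 0")
  p <- tryCatch(wilcoxon_signed_rank(a - b)$p.value,
                error = function(e) NA_real_)
  list(ratio = mean(a) / mb, mean_a = mean(a), mean_b = mb, p.value = p)
}
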