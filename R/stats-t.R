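#' Paired t-test on a vector of paired differences
#'
#' Computes `t = mean(d) / (sd(d) / sqrt(n))` with `df = n - 1` and a
#' two-sided p-value from the Student-t tail, returning the mean difference
#' and its standard error. A zero-variance input with non-zero mean is
#' flagged as an infinite-t degenerate case (p = 0); zero variance with zero
#' mean gives t = 0, p = 1.
#'
#' @param diffs Numeric vector of paired differences (mm Hg); `n >= 2`.
#' @param label Optional description carried in the result.
#' @return An object of class `iop_ttest`: list with `statistic`, `df`, `p`,
#'   `estimate`, `sem`, `n`, `infinite`, `method`.
#' @export
paired_t <- function(diffs, label = "paired t-test") {
  d <- diffs[!is.na(diffs)]
  n <- length(d)
  if (n < 2L) stop("paired_t needs at least 2 paired differences")
  m <- mean(d)
  s <- stats::sd(d)
  inf_flag <- FALSE
  if (s == 0) {
    if (m == 0) { tstat <- 0; p <- 1 } else { tstat <- Inf * sign(m); p <- 0; inf_flag <- TRUE }
    sem <- 0
  } else {
    sem <- s / sqrt(n)
    tstat <- m / sem
    p <- 2 * stats::pt(-abs(tstat), df = n - 1L)
  }
  structure(list(statistic = tstat, df = n - 1L, p = p, estimate = m,
                 sem = sem, n = n, infinite = inf_flag, method = label),
            class = "iop_ttest")
}

#' One-sample t-test against a reference value
#'
#' Identical to [paired_t()] applied to `x - mu0`.
#'
#' @param x Numeric vector; `n >= 2`.
#' @param mu0 Null value (default 0).
#' @param label Optional description.
#' @return An `iop_ttest` object.
#' @export
one_sample_t <- function(x, mu0 = 0, label = "one-sample t-test") {
  paired_t(x - mu0, label = label)
}

#' @export
print.iop_ttest <- function(x, ...) {
  cat(sprintf("%s: estimate %.3f +/- %.3f mm Hg (n = %d), t(%d) = %.3f, p = %.4g%s\n",
              x$method, x$estimate, x$sem, x$n, x$df, x$statistic, x$p,
              if (isTRUE(x$infinite)) " [zero-variance: infinite t]" else ""))
  invisible(x)
}

#' Bonferroni-Holm step-down multiplicity control
#'
#' P-values are sorted ascending (ties broken by original index); the k-th
#' smallest is compared against the threshold `alpha / (m - k + 1)`.
#' Rejection proceeds step-down: the first rank whose p-value exceeds its
#' threshold stops the procedure, and all later ranks are retained. Holm
#' adjusted p-values (`cummax` of `(m - k + 1) * p`, capped at 1) are also
#' returned. Thresholds are additionally reported rounded to three decimals,
#' the convention used when quoting the adjusted alpha next to a p-value.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error level (default 0.05).
#' @return An object of class `holm_result`: data frame with one row per
#'   test in the original order (`p`, `rank`, `threshold`,
#'   `threshold_rounded`, `reject`, `p_adj`), with the family size and alpha
#'   as attributes.
#' @export
holm_adjust <- function(pvals, alpha = 0.05) {
  m <- length(pvals)
  if (m == 0L) stop("empty p-value list")
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("all p-values must lie in [0, 1]")
  ord <- order(pvals, seq_len(m))   # stable: ties by original index
  ps <- pvals[ord]
  thr <- alpha / (m - seq_len(m) + 1)
  ok <- ps <= thr
  fail <- which(!ok)
  reject_sorted <- if (length(fail)) seq_len(m) < fail[1L] else rep(TRUE, m)
  padj_sorted <- pmin(1, cummax((m - seq_len(m) + 1) * ps))
  out <- data.frame(p = pvals, rank = NA_integer_, threshold = NA_real_,
                    threshold_rounded = NA_real_, reject = NA, p_adj = NA_real_)
  out$rank[ord] <- seq_len(m)
  out$threshold[ord] <- thr
  out$threshold_rounded <- round(out$threshold, 3)
  out$reject[ord] <- reject_sorted
  out$p_adj[ord] <- padj_sorted
  structure(out, class = c("holm_result", "data.frame"),
            m = m, alpha = alpha)
}

#' @export
print.holm_result <- function(x, ...) {
  cat(sprintf("Bonferroni-Holm step-down, m = %d, alpha = %g: %d of %d rejected\n",
              attr(x, "m"), attr(x, "alpha"), sum(x$reject), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Least-squares linear correlation
#'
#' Simple linear regression of `y` on `x` with the coefficient of
#' determination and a two-sided p-value from the t-statistic on the slope.
#'
#' @param x,y Numeric vectors, `n >= 3`; `x` must have positive variance.
#' @return An object of class `iop_corr`: list with `slope`, `intercept`,
#'   `r_squared`, `statistic`, `df`, `p`, `n`.
#' @export
linear_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("linear_corr needs at least 3 complete pairs")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("x has zero variance")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- syy - slope * sxy
  r2 <- if (syy > 0) 1 - rss / syy else NA_real_
  se <- sqrt(max(rss, 0) / (n - 2L) / sxx)
  tstat <- if (se > 0) slope / se else Inf * sign(slope)
  p <- if (is.finite(tstat)) 2 * stats::pt(-abs(tstat), df = n - 2L) else 0
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 statistic = tstat, df = n - 2L, p = p, n = n),
            class = "iop_corr")
}

#' @export
print.iop_corr <- function(x, ...) {
  cat(sprintf("linear fit: y = %.3f + %.3f x, R^2 = %.3f, t(%d) = %.3f, p = %.4g (n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$df, x$statistic, x$p, x$n))
  invisible(x)
}

#' Shapiro-Wilk normality screen
#'
#' Advisory normality check used before the parametric analyses; the
#' pipeline proceeds regardless of the outcome and only records the result.
#'
#' @param x Numeric vector with `3 <= n <= 5000`.
#' @return A list with `W`, `p` and a `degenerate` flag (constant input, no
#'   test possible).
#' @export
normality_screen <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L || n > 5000L)
    stop("normality_screen requires 3 <= n <= 5000")
  if (stats::sd(x) == 0)
    return(list(W = NA_real_, p = NA_real_, degenerate = TRUE))
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value, degenerate = FALSE)
}
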