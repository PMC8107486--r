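#' Greenhouse-Geisser epsilon from a contrast covariance
#'
#' For a within-subject effect with `k` levels entering sphericity, let `C`
#' be the `(k - 1) x (k - 1)` covariance matrix of the orthonormal
#' within-subject contrasts. The sphericity correction factor is
#' \deqn{\epsilon = \frac{(\mathrm{tr}\, C)^2}{(k-1)\,\mathrm{tr}(C^2)}
#'   = \frac{(\sum_i \lambda_i)^2}{(k-1)\sum_i \lambda_i^2}}
#' over the eigenvalues of `C`, clipped to the admissible range
#' `[1/(k-1), 1]`. Equal eigenvalues (sphericity) give 1; a single non-zero
#' eigenvalue gives the lower bound.
#'
#' @param contrast_cov Symmetric positive semi-definite matrix of size
#'   `(k - 1)`.
#' @return Epsilon in `[1/(k-1), 1]`.
#' @export
gg_epsilon <- function(contrast_cov) {
  C <- as.matrix(contrast_cov)
  if (nrow(C) != ncol(C)) stop("contrast covariance must be square")
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    stop("contrast covariance must be symmetric")
  d <- nrow(C)
  tr <- sum(diag(C))
  tr2 <- sum(C * C)
  if (tr2 <= 0) return(1)       # null covariance: no sphericity question
  eps <- tr^2 / (d * tr2)
  min(1, max(1 / d, eps))
}

# Orthonormal contrasts spanning the space orthogonal to the constant:
# normalised Helmert columns.
.ortho_contrasts <- function(k) {
  m <- stats::contr.helmert(k)
  m %*% diag(1 / sqrt(colSums(m^2)), ncol(m), ncol(m))
}

#' Fully within-subject repeated-measures ANOVA with GG correction
#'
#' Decomposes a complete balanced table of responses (one value per subject
#' and within-factor cell) into all main effects and interactions of the
#' within factors, treating subjects as the random blocking factor. Each
#' within effect `E` is tested against its own subject-interaction error
#' term: `F = MS_E / MS_(E x subject)`. For every effect with more than one
#' degree of freedom a Greenhouse-Geisser epsilon is estimated from the
#' covariance of that effect's orthonormal within-subject contrasts
#' (averaging over the factors not involved), and a sphericity-corrected
#' p-value `p_gg` is reported alongside the uncorrected one (effects with a
#' single df have epsilon 1 by construction).
#'
#' Missing cells are imputed by the subject's mean over the remaining
#' repetitions of the same condition (falling back to the subject mean) and
#' the number of imputations is recorded in the `n_imputed` attribute;
#' degrees of freedom are not adjusted. A constant response yields zero
#' effect sums of squares and undefined F (reported as `NA`).
#'
#' @param data Data frame with the response and factor columns.
#' @param dv Name of the response column (default `"delta_iop"`).
#' @param subject Name of the subject column (default `"patient_id"`).
#' @param within Character vector of within-subject factor columns (default
#'   `c("direction", "eccentricity_deg", "repetition")`).
#' @return An object of class `iop_rm_anova`: data frame with one row per
#'   effect (`effect`, `df`, `SS`, `MS`, `error_SS`, `error_df`,
#'   `error_MS`, `F`, `epsilon`, `p`, `p_gg`), with attributes
#'   `n_subjects`, `subject_SS`, `total_SS`, `n_imputed`.
#' @export
rm_anova_within <- function(data, dv = "delta_iop", subject = "patient_id",
                            within = c("direction", "eccentricity_deg",
                                       "repetition")) {
  cols <- c(subject, within, dv)
  if (!all(cols %in% names(data)))
    stop("data must have columns: ", paste(cols, collapse = ", "))
  g <- data[, cols]
  # factors observed at a single level carry no within-subject information
  keep <- vapply(within, function(f) length(unique(g[[f]])) > 1L, TRUE)
  if (!any(keep)) stop("no within factor has more than one level")
  within <- within[keep]
  g <- g[, c(subject, within, dv)]
  names(g) <- c("S", paste0("W", seq_along(within)), "y")
  fac <- c("S", paste0("W", seq_along(within)))
  for (f in fac) g[[f]] <- factor(g[[f]])
  if (nlevels(g$S) < 2L) stop("at least 2 subjects are required")
  # collapse duplicates to cell means, then complete the grid
  g <- aggregate(y ~ ., g, mean)
  full <- expand.grid(lapply(g[fac], levels), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = TRUE)
  names(full) <- fac
  g <- merge(full, g, all.x = TRUE, sort = FALSE)
  n_imp <- sum(is.na(g$y))
  if (n_imp > 0) {
    # impute by the subject's same-condition mean over the other levels of
    # the last within factor (the repetition factor in the standard design)
    cond <- fac[-length(fac)]
    condmean <- ave(g$y, g[cond], FUN = function(z) mean(z, na.rm = TRUE))
    submean <- ave(g$y, g$S, FUN = function(z) mean(z, na.rm = TRUE))
    miss <- is.na(g$y)
    g$y[miss] <- ifelse(is.finite(condmean[miss]), condmean[miss],
                        submean[miss])
    if (anyNA(g$y)) stop("subject with no observations at all; cannot impute")
  }

  nlev <- vapply(g[fac], nlevels, 1L)
  names(nlev) <- fac
  # balanced orthogonal decomposition on the full grid: effect estimates by
  # inclusion-exclusion over factor subsets; SS = sum of squared estimates
  subsets <- lapply(seq_len(2^length(fac)) - 1L, function(b)
    fac[bitwAnd(b, 2^(seq_along(fac) - 1L)) > 0])
  subsets <- subsets[order(lengths(subsets))]
  eff <- list()
  key <- function(s) if (length(s)) paste(sort(s), collapse = ":") else ".grand"
  for (T in subsets) {
    mT <- if (length(T) == 0L) rep(mean(g$y), nrow(g))
          else ave(g$y, g[T], FUN = mean)
    eT <- mT
    for (U in subsets[lengths(subsets) < length(T)])
      if (all(U %in% T)) eT <- eT - eff[[key(U)]]
    eff[[key(T)]] <- eT
  }
  SS <- vapply(eff, function(e) sum(e^2), 0)
  dfs <- vapply(subsets, function(T)
    prod(nlev[T] - 1L) * (length(T) > 0L), 0)
  names(dfs) <- vapply(subsets, key, "")

  wfac <- fac[-1L]
  wsubsets <- subsets[lengths(subsets) > 0 &
                        vapply(subsets, function(T) !"S" %in% T, TRUE)]
  rows <- NULL
  for (E in wsubsets) {
    kE <- key(E); kErr <- key(c("S", E))
    df1 <- dfs[[kE]]; df2 <- dfs[[kErr]]
    msE <- SS[[kE]] / df1; msErr <- SS[[kErr]] / df2
    Fv <- if (msErr > 0) msE / msErr else NA_real_
    p <- if (is.na(Fv)) NA_real_ else stats::pf(Fv, df1, df2, lower.tail = FALSE)
    eps <- if (df1 > 1) .effect_epsilon(g, E, nlev) else 1
    p_gg <- if (is.na(Fv)) NA_real_ else
      stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
    rows <- rbind(rows, data.frame(
      effect = paste(within[match(E, paste0("W", seq_along(within)))],
                     collapse = ":"),
      df = df1, SS = SS[[kE]], MS = msE,
      error_SS = SS[[kErr]], error_df = df2, error_MS = msErr,
      F = Fv, epsilon = eps, p = p, p_gg = p_gg,
      stringsAsFactors = FALSE))
  }
  structure(rows, class = c("iop_rm_anova", "data.frame"),
            n_subjects = nlevels(g$S),
            subject_SS = SS[["S"]], subject_df = dfs[["S"]],
            total_SS = sum((g$y - mean(g$y))^2),
            n_imputed = n_imp)
}

# GG epsilon for one effect: covariance across subjects of the effect's
# orthonormal contrast scores, computed on cell means averaged over the
# uninvolved within factors.
.effect_epsilon <- function(g, E, nlev) {
  n <- nlev[["S"]]
  M <- tapply(g$y, g[c("S", E)], mean)       # array: subject x levels(E)
  M <- matrix(M, nrow = n)                   # columns: first factor fastest
  Qs <- lapply(E, function(f) .ortho_contrasts(nlev[[f]]))
  Q <- Reduce(kronecker, rev(Qs))
  C <- stats::cov(M %*% Q)
  gg_epsilon(C)
}

#' @export
print.iop_rm_anova <- function(x, ...) {
  cat(sprintf("Within-subject repeated-measures ANOVA (%d subjects%s)\n",
              attr(x, "n_subjects"),
              if (attr(x, "n_imputed") > 0)
                sprintf(", %d cell(s) imputed", attr(x, "n_imputed")) else ""))
  df <- as.data.frame(x)
  df$SS <- signif(df$SS, 5); df$MS <- signif(df$MS, 5)
  df$error_SS <- signif(df$error_SS, 5); df$error_MS <- signif(df$error_MS, 5)
  df$F <- signif(df$F, 4); df$epsilon <- round(df$epsilon, 3)
  df$p <- signif(df$p, 3); df$p_gg <- signif(df$p_gg, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
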