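#' @export
print.iop_gaze_fit <- function(x, ...) {
  cat(sprintf("<iop_gaze_fit> %d patient(s), %d response records (%d QC-excluded)\n",
              x$n_patients, nrow(x$records), sum(!x$records$qc_pass)))
  if (!is.null(x$anova)) {
    a <- as.data.frame(x$anova)
    key <- a[a$effect %in% c("direction", "direction:eccentricity_deg"), ]
    for (i in seq_len(nrow(key)))
      cat(sprintf("  %s: F(%g, %g) = %.2f, eps = %.2f, p_GG = %.4g\n",
                  key$effect[i], key$df[i], key$error_df[i], key$F[i],
                  key$epsilon[i], key$p_gg[i]))
  }
  if (!is.null(x$eyelid_test))
    cat(sprintf("  eyelid vs downgaze: %.2f +/- %.2f mm Hg, p = %.3g\n",
                x$eyelid_test$estimate, x$eyelid_test$sem, x$eyelid_test$p))
  invisible(x)
}

#' Summarise a fitted gaze-IOP analysis
#'
#' Prints the condition-level group table (mean +/- SEM per direction and
#' eccentricity with the Overall rows), the within-subject ANOVA table, the
#' Holm-corrected post-hoc contrasts, and the eyelid, control and
#' individual-level results where available.
#'
#' @param object An `iop_gaze_fit`.
#' @param ... Unused.
#' @return `object`, invisibly.
#' @export
summary.iop_gaze_fit <- function(object, ...) {
  cat("Condition-level IOP responses (mm Hg, mean over repetitions):\n")
  g <- object$group_summary
  g[] <- lapply(g, function(c) if (is.numeric(c)) round(c, 2) else c)
  print(g, row.names = FALSE)
  if (!is.null(object$anova)) { cat("\n"); print(object$anova) }
  if (!is.null(object$posthoc)) {
    cat("\nPost-hoc one-sample t-tests (Holm-corrected per eccentricity):\n")
    ph <- object$posthoc
    ph[] <- lapply(ph, function(c) if (is.numeric(c)) signif(c, 3) else c)
    print(ph, row.names = FALSE)
  }
  if (!is.null(object$tw_correlation)) {
    cat("\nTime-course: TW_initial vs dDeltaIOP across conditions: ")
    print(object$tw_correlation)
  }
  if (!is.null(object$control)) {
    cat("\nInternal control (first vs closing superior gaze):\n")
    print(object$control, row.names = FALSE)
  }
  if (!is.null(object$eyelid_test)) { cat("\n"); print(object$eyelid_test) }
  if (!is.null(object$individual))
    cat(sprintf("\nIndividual extreme-direction contrast: %d of %d patients significant at %.2g\n",
                attr(object$individual, "n_significant"),
                sum(!object$individual$skipped), object$alpha))
  invisible(object)
}

#' Estimated condition-level responses of a fit
#'
#' @param object An `iop_gaze_fit`.
#' @param ... Unused.
#' @return Numeric matrix of group-mean responses (mm Hg), directions in
#'   rows, eccentricities in columns.
#' @export
coef.iop_gaze_fit <- function(object, ...) {
  g <- object$group_summary[object$group_summary$direction != "Overall", ]
  eccs <- sort(unique(g$eccentricity_deg))
  out <- matrix(NA_real_, length(GAZE_LABELS), length(eccs),
                dimnames = list(GAZE_LABELS, as.character(eccs)))
  out[cbind(g$direction, as.character(g$eccentricity_deg))] <- g$delta_mean
  out
}

#' Plot condition-level IOP responses
#'
#' Group-mean response with SEM bars per gaze direction, one line per
#' eccentricity.
#'
#' @param x An `iop_gaze_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.iop_gaze_fit <- function(x, ...) {
  g <- x$group_summary[x$group_summary$direction != "Overall", ]
  eccs <- sort(unique(g$eccentricity_deg))
  m <- coef(x)
  graphics::matplot(seq_along(GAZE_LABELS), m, type = "b", pch = 19,
                    lty = 1, xaxt = "n", xlab = "gaze direction",
                    ylab = expression(Delta * IOP ~ "(mm Hg)"), ...)
  graphics::axis(1, at = seq_along(GAZE_LABELS), labels = GAZE_LABELS)
  graphics::abline(h = 0, lty = 3)
  for (j in seq_along(eccs)) {
    ge <- g[g$eccentricity_deg == eccs[j], ]
    i <- match(ge$direction, GAZE_LABELS)
    graphics::arrows(i, ge$delta_mean - ge$delta_sem,
                     i, ge$delta_mean + ge$delta_sem,
                     angle = 90, code = 3, length = 0.03, col = j)
  }
  graphics::legend("topright", legend = paste0(eccs, "°"), col =
                     seq_along(eccs), lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' Simulate response tables from a fitted analysis
#'
#' Draws new per-record responses from a normal model with the fit's
#' condition means and the residual spread of the observed records —
#' a quick parametric bootstrap of the response table.
#'
#' @param object An `iop_gaze_fit`.
#' @param nsim Number of simulated tables (default 1).
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `nsim` data frames shaped like `object$records`.
#' @export
simulate.iop_gaze_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  r <- object$records[object$records$qc_pass & !object$records$is_control, ]
  g <- object$group_summary[object$group_summary$direction != "Overall", ]
  mu <- g$delta_mean[match(paste(r$direction, r$eccentricity_deg),
                           paste(g$direction, g$eccentricity_deg))]
  sigma <- stats::sd(r$delta_iop - mu)
  lapply(seq_len(nsim), function(i) {
    out <- r
    out$delta_iop <- stats::rnorm(nrow(r), mu, sigma)
    out
  })
}

#' Residual responses of a fitted analysis
#'
#' @param object An `iop_gaze_fit`.
#' @param ... Unused.
#' @return Numeric vector: record-level response minus its condition group
#'   mean (quality-passing, non-control records).
#' @export
residuals.iop_gaze_fit <- function(object, ...) {
  r <- object$records[object$records$qc_pass & !object$records$is_control, ]
  g <- object$group_summary[object$group_summary$direction != "Overall", ]
  mu <- g$delta_mean[match(paste(r$direction, r$eccentricity_deg),
                           paste(g$direction, g$eccentricity_deg))]
  stats::setNames(r$delta_iop - mu,
                  paste(r$patient_id, r$direction, r$eccentricity_deg,
                        r$repetition, sep = "."))
}
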