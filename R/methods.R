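#' @export
print.drgsd <- function(x, digits = 3, ...) {
  b <- x$boundaries
  cat(sprintf("%s: two-stage error-spending design (%s spending)\n",
              x$spec$design_kind, x$spec$spending_family))
  cat(sprintf("  continuation region (l1, u1) = (%.*f, %.*f)\n",
              digits, b[["l1"]], digits, b[["u1"]]))
  if (!is.na(b[["d1"]]))
    cat(sprintf("  interim decision value d1 = %.*f\n", digits, b[["d1"]]))
  cat(sprintf("  final critical value d2 = %.*f\n", digits, b[["d2"]]))
  cat(sprintf("  interim spends: alpha1 = %.4f, beta1 = %.4f\n",
              x$alpha1, x$beta1))
  cat(sprintf("  calibrated design alternative delta~ = %.4f (power %.2f)\n",
              x$delta_tilde, 1 - x$spec$beta))
  invisible(x)
}

#' Decision boundaries of a solved design
#'
#' @param object a fitted [drgsd()] design.
#' @param ... unused.
#' @return Named vector `c(l1, u1, d1, d2)` on the z-scale (`d1` is `NA` for
#'   the standard GSD, which has no interim decision value).
#' @export
coef.drgsd <- function(object, ...) object$boundaries

#' Defining-equation residuals of a solved design
#'
#' Residuals, on the probability scale, of every equation that defines the
#' boundary set: the interim and final error spends, the lower-boundary
#' type-II spend at the calibrated alternative, the total-power calibration,
#' and (DR-GSD) the interim balance equation.  All should be below `1e-6` in
#' absolute value for a converged solve.
#'
#' @param object a fitted [drgsd()] design.
#' @param ... unused.
#' @return Named numeric vector of residuals.
#' @export
residuals.drgsd <- function(object, ...) object$diagnostics

#' @export
summary.drgsd <- function(object, delta = NULL, ...) {
  structure(list(fit = object,
                 performance = performance(object, delta),
                 max_residual = max(abs(object$diagnostics))),
            class = "summary.drgsd")
}

#' @export
print.summary.drgsd <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  s <- x$fit$sizes
  cat(sprintf(
    "  per-arm sizes: n1 = %.1f, pipeline = %.1f, decision = %.1f, max = %.1f\n",
    s$n1, s$n_pipeline, s$n1_tilde, s$n_max))
  cat(sprintf("  max |defining-equation residual| = %.2e\n\n", x$max_residual))
  cat("Operating characteristics:\n")
  p <- x$performance
  p[-(1:4)] <- round(p[-(1:4)], digits)
  print(p[, -(2:4)], row.names = FALSE)
  invisible(x)
}

#' One-row data frame view of a solved design
#'
#' Mirrors the boundary-table serialization: design, spending family,
#' information fractions, boundaries, interim spends and the calibrated
#' alternative.
#'
#' @param x a fitted [drgsd()] design.
#' @param ... unused.
#' @export
as.data.frame.drgsd <- function(x, ...) {
  data.frame(design = x$spec$design_kind,
             spending_family = x$spec$spending_family,
             info_interim = x$spec$info_interim,
             info_pipeline = x$spec$info_pipeline,
             t(x$boundaries), alpha1 = x$alpha1, beta1 = x$beta1,
             delta_tilde = x$delta_tilde, row.names = NULL)
}

#' Plot operating characteristics of a solved design
#'
#' Base-graphics curves of power, interim rejection and futility
#' probabilities over a grid of effect sizes.
#'
#' @param x a fitted [drgsd()] design.
#' @param delta effect-size grid; defaults to a symmetric range around the
#'   calibrated alternative.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.drgsd <- function(x, delta = NULL, ...) {
  if (is.null(delta))
    delta <- seq(-0.5 * x$delta_tilde, 1.5 * x$delta_tilde, length.out = 41)
  p <- performance(x, delta)
  graphics::matplot(p$delta, p[, c("power", "p_reject_interim", "p_futility")],
                    type = "l", lty = 1:3, col = c("black", "blue", "red"),
                    xlab = expression(delta), ylab = "probability",
                    main = paste0(x$spec$design_kind, " operating characteristics"),
                    ...)
  graphics::legend("left", c("power", "reject at interim", "futility"),
                   lty = 1:3, col = c("black", "blue", "red"), bty = "n")
  invisible(p)
}
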