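#' Canonical multivariate normal model of the sequential test statistics
#'
#' The interim statistic \eqn{Z_1}, the decision-analysis statistic
#' \eqn{\tilde Z_1} (interim plus pipeline data) and the final inverse-normal
#' combination \eqn{Z_{1+2}} jointly follow the canonical multivariate normal
#' law of group-sequential theory: unit variances, correlations
#' \eqn{\sqrt{I_a/I_b}} for information fractions \eqn{I_a \le I_b}, and mean
#' (drift) \eqn{(\delta/\sigma)\sqrt{I_k\, n_{max}/2}} at information level
#' \eqn{I_k}.  Information levels here are \eqn{(I_1,\ \tilde I_1 = I_1 +
#' I_{\Delta t},\ 1)}.
#'
#' The inverse-normal weights are fixed at the planning stage as
#' \eqn{w_1 = \sqrt{n_1/n_{max}}}, \eqn{w_2 = \sqrt{1 - n_1/n_{max}}}, so the
#' combination statistic coincides with the all-data z-statistic and the
#' canonical correlation structure applies.
#'
#' @param spec a [design_spec()].
#' @return Object of class `"drgsd_canonical"`: list with `info` (the three
#'   information levels), `corr` (3x3 correlation matrix with dimnames
#'   `Z1`, `Z1_tilde`, `Z12`), `drift(delta)` (mean vector at effect `delta`,
#'   in outcome units), and `weights` (`w1`, `w2`).
#' @examples
#' m <- canonical_model(design_spec(info_interim = 0.29, info_pipeline = 0.3))
#' m$corr
#' m$drift(0)  # zero under the null
#' @export
canonical_model <- function(spec) {
  spec <- as_spec(spec)
  info <- c(Z1 = spec$info_interim,
            Z1_tilde = spec$info_interim + spec$info_pipeline,
            Z12 = 1)
  if (info[2L] >= 1)
    stop("invalid design: interim + pipeline information reaches 1",
         call. = FALSE)
  corr <- sqrt(outer(info, info, pmin) / outer(info, info, pmax))
  dimnames(corr) <- list(names(info), names(info))
  n_max <- spec$n_max
  sigma <- spec$sigma
  drift <- function(delta) (delta / sigma) * sqrt(info * n_max / 2)
  w1 <- sqrt(spec$info_interim)
  structure(list(info = info, corr = corr, drift = drift,
                 weights = c(w1 = w1, w2 = sqrt(1 - w1^2))),
            class = "drgsd_canonical")
}

#' @export
print.drgsd_canonical <- function(x, ...) {
  cat("Canonical MVN model; information levels:",
      paste(signif(x$info, 4), collapse = ", "), "\n")
  print(round(x$corr, 4))
  invisible(x)
}

#' Multivariate normal rectangle probability
#'
#' \eqn{P(\mathrm{lower} < X < \mathrm{upper})} for a multivariate normal
#' vector of dimension 1 to 3 with the given mean and correlation matrix.
#' Dimension 1 uses `pnorm` directly; dimensions 2 and 3 use the deterministic
#' Miwa lattice algorithm of \pkg{mvtnorm}, accurate to well below `1e-7` at
#' these dimensions.  Infinite limits are allowed.
#'
#' @param lower,upper rectangle limits (`-Inf`/`Inf` allowed), length 1-3.
#' @param mean mean vector (recycled scalar allowed).
#' @param corr correlation matrix (unit diagonal, positive semi-definite);
#'   ignored for dimension 1.
#' @return The rectangle probability as a bare number.
#' @examples
#' mvn_rect_prob(-Inf, 1.96)                       # 0.975
#' mvn_rect_prob(c(0, 0), c(Inf, Inf), corr = diag(2))  # 0.25
#' @export
mvn_rect_prob <- function(lower, upper, mean = 0, corr = NULL) {
  d <- length(lower)
  if (d < 1L || d > 3L || length(upper) != d)
    stop("'lower' and 'upper' must have equal length between 1 and 3",
         call. = FALSE)
  mean <- rep_len(mean, d)
  if (any(lower >= upper))
    stop("'lower' must be elementwise below 'upper'", call. = FALSE)
  if (d == 1L)
    return(pnorm(upper - mean) - pnorm(lower - mean))
  if (is.null(corr)) corr <- diag(d)
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-10)) ||
      any(abs(diag(corr) - 1) > 1e-10))
    stop("'corr' must be a symmetric correlation matrix", call. = FALSE)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("'corr' is not positive semi-definite", call. = FALSE)
  # Miwa is deterministic; clamp infinite limits far outside the support so
  # the lattice never sees Inf
  lim <- 12 + max(abs(mean))
  p <- mvtnorm::pmvnorm(lower = pmax(lower, -lim), upper = pmin(upper, lim),
                        mean = mean, corr = corr,
                        algorithm = mvtnorm::Miwa(steps = 4097))
  max(0, min(1, as.numeric(p)))
}

# bivariate helper used throughout the solvers: P(lo < (X1,X2) < hi) with
# correlation r
.p2 <- function(lo, hi, mean, r) {
  mvn_rect_prob(lo, hi, mean, matrix(c(1, r, r, 1), 2L))
}
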