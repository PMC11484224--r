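#' Solve a two-stage error-spending design with delayed responses
#'
#' `drgsd()` is the package's fitting function.  Given the trial parameters it
#' solves the decision boundary set and the calibrated design alternative for
#' one of three two-stage designs, all with *nonbinding* lower (futility /
#' recruitment-stop) boundaries:
#'
#' * **GSD** — standard error-spending group-sequential design ignoring
#'   pipeline data for decisions: stop for efficacy if \eqn{Z_1 \ge u_1}, for
#'   futility if \eqn{Z_1 \le l_1}, final rejection if \eqn{Z_{1+2} \ge d_2}.
#' * **DR_GSD** — the Hampson-Jennison delayed-response design: crossing
#'   \eqn{(l_1, u_1)} stops *recruitment* only; the interim efficacy decision
#'   is then taken on the enlarged statistic \eqn{\tilde Z_1 \ge d_1}, where
#'   `d1` balances \eqn{P_0(Z_1 \ge u_1, \tilde Z_1 < d_1) =
#'   P_0(Z_1 \le l_1, \tilde Z_1 \ge d_1)} so that the full type-I error is
#'   exhausted.  `{l1, u1, d2}` coincide with the GSD's.
#' * **RR_GSD** — the repeated-rejection variant (Jennison-Hampson): interim
#'   rejection requires both \eqn{Z_1 \ge u_1} *and* the confirmation
#'   \eqn{\tilde Z_1 \ge d_1} with \eqn{d_1 = \Phi^{-1}(1-\alpha)} fixed;
#'   \eqn{u_1} then satisfies \eqn{P_0(Z_1 \ge u_1, \tilde Z_1 \ge d_1) =
#'   \alpha_1}, and the interim type-II spend covers both
#'   \eqn{Z_1 \le l_1} and \eqn{\{Z_1 \ge u_1, \tilde Z_1 < d_1\}}.
#'
#' Interim error spends \eqn{\alpha_1, \beta_1} come from the error-spending
#' family evaluated at `info_interim`.  In all designs \eqn{d_2} is computed
#' assuming continuation whenever \eqn{Z_1 < u_1} (the lower boundary is
#' nonbinding), and the design alternative \eqn{\tilde\delta} is calibrated so
#' the design's total power at \eqn{\tilde\delta} is exactly `1 - beta` at the
#' fixed `n_max`; the lower boundary then satisfies the interim type-II spend
#' equation at \eqn{\tilde\delta}.
#'
#' @param design_kind,alpha,beta,sigma,n_max,info_interim,info_pipeline,spending_family
#'   design parameters, see [design_spec()].
#' @param spec alternatively, a ready-made [design_spec()]; overrides the
#'   individual arguments.
#' @return An object of class `"drgsd"`; a list with components
#'   `spec`, `model` (the [canonical_model()]), `sizes`
#'   ([sample_size_plan()]), `boundaries` (named vector `l1,u1,d1,d2`; `d1` is
#'   `NA` for the GSD), `alpha1`, `beta1`, `delta_tilde` (calibrated design
#'   alternative, outcome units), and `diagnostics` (defining-equation
#'   residuals, probability scale).  Methods: [print.drgsd()],
#'   [summary.drgsd()], [coef.drgsd()], [residuals.drgsd()],
#'   [performance()], [simulate.drgsd()], [plot.drgsd()].
#' @references Hampson, L.V. and Jennison, C. (2013). Group sequential tests
#'   for delayed responses (with discussion). *JRSS-B* 75, 3-54.
#' @examples
#' # schizophrenia-trial worked example (Mehta & Pocock recruitment scenario)
#' fit <- drgsd("DR_GSD", alpha = 0.025, beta = 0.2, sigma = 7.5, n_max = 345,
#'              info_interim = 0.29, info_pipeline = 0.3)
#' coef(fit)
#' @export
drgsd <- function(design_kind = "GSD", alpha = 0.025, beta = 0.2, sigma = 1,
                  n_max = 200, info_interim = 0.5, info_pipeline = 0,
                  spending_family = "pocock_like", spec = NULL) {
  if (is.null(spec))
    spec <- design_spec(alpha, beta, sigma, n_max, info_interim,
                        info_pipeline, spending_family, design_kind)
  else spec <- as_spec(spec)
  model <- canonical_model(spec)
  sol <- switch(spec$design_kind,
                GSD = .solve_gsd(spec, model),
                DR_GSD = .solve_drgsd(spec, model),
                RR_GSD = .solve_rrgsd(spec, model))
  structure(c(list(spec = spec, model = model,
                   sizes = sample_size_plan(spec)), sol),
            class = "drgsd")
}

# root-finding conventions: all z-scale roots bracketed on [-10, 10],
# standardized-effect roots on (0, theta_max] with final drift <= 10
.zbracket <- c(-10, 10)
.ztol <- 1e-10

.root <- function(f, interval, ...) {
  r <- uniroot(f, interval, tol = .ztol, ...)
  r$root
}

# shared GSD/DR-GSD spending system: u1 from the interim alpha spend, d2 from
# the final alpha spend ignoring l1 (nonbinding), then (l1, delta_tilde) from
# the beta-spending / total-power system
.solve_gsd_core <- function(spec, model) {
  inc_a <- spend_increments(spec$info_interim, spec$alpha,
                            spec$spending_family)
  inc_b <- spend_increments(spec$info_interim, spec$beta,
                            spec$spending_family)
  a1 <- inc_a[["interim"]]; b1 <- inc_b[["interim"]]
  r13 <- model$corr["Z1", "Z12"]
  u1 <- qnorm(1 - a1)
  d2 <- .root(function(d)
    .p2(c(-Inf, d), c(u1, Inf), c(0, 0), r13) - (spec$alpha - a1),
    .zbracket)
  cal <- .calibrate(spec, model, u1, d2, b1,
                    l1_fun = function(theta)
                      qnorm(b1) + theta * sqrt(spec$info_interim *
                                               spec$n_max / 2))
  list(a1 = a1, b1 = b1, u1 = u1, d2 = d2, l1 = cal$l1, theta = cal$theta)
}

# calibrate the standardized design alternative theta = delta_tilde / sigma so
# that the residual stage-2 type-II error equals beta - beta1; l1_fun gives
# the interim lower boundary implied by the design's own beta1-spend equation
.calibrate <- function(spec, model, u1, d2, b1, l1_fun) {
  r13 <- model$corr["Z1", "Z12"]
  n2 <- spec$n_max / 2
  theta_max <- 10 / sqrt(n2)       # final-analysis drift capped at 10
  resid <- function(theta) {
    l1 <- l1_fun(theta)
    if (!is.finite(l1)) return(NA_real_)
    if (l1 >= u1) return(-(spec$beta - b1))   # continuation region empty
    m <- theta * sqrt(c(spec$info_interim, 1) * n2)
    .p2(c(l1, -Inf), c(u1, d2), m, r13) - (spec$beta - b1)
  }
  lo <- 1e-8
  if (!is.finite(resid(lo)) || resid(lo) < 0)
    stop("design alternative calibration failed at the lower bracket",
         call. = FALSE)
  if (resid(theta_max) > 0)
    stop("no design alternative with final drift below 10; ",
         "the design cannot reach the target power", call. = FALSE)
  theta <- .root(resid, c(lo, theta_max))
  list(theta = theta, l1 = l1_fun(theta))
}

.solve_gsd <- function(spec, model) {
  core <- .solve_gsd_core(spec, model)
  out <- list(boundaries = c(l1 = core$l1, u1 = core$u1, d1 = NA_real_,
                             d2 = core$d2),
              alpha1 = core$a1, beta1 = core$b1,
              delta_tilde = core$theta * spec$sigma)
  out$diagnostics <- .residuals_for(spec, model, out)
  out
}

.solve_drgsd <- function(spec, model) {
  core <- .solve_gsd_core(spec, model)
  r12 <- model$corr["Z1", "Z1_tilde"]
  # Eq.-style balance: P0(Z1 >= u1, Z1~ < d1) = P0(Z1 <= l1, Z1~ >= d1);
  # strictly increasing in d1, so a plain bracketed root suffices
  bal <- function(d)
    .p2(c(core$u1, -Inf), c(Inf, d), c(0, 0), r12) -
    .p2(c(-Inf, d), c(core$l1, Inf), c(0, 0), r12)
  d1 <- .root(bal, .zbracket)
  out <- list(boundaries = c(l1 = core$l1, u1 = core$u1, d1 = d1,
                             d2 = core$d2),
              alpha1 = core$a1, beta1 = core$b1,
              delta_tilde = core$theta * spec$sigma)
  out$diagnostics <- .residuals_for(spec, model, out)
  out
}

.solve_rrgsd <- function(spec, model) {
  inc_a <- spend_increments(spec$info_interim, spec$alpha,
                            spec$spending_family)
  inc_b <- spend_increments(spec$info_interim, spec$beta,
                            spec$spending_family)
  a1 <- inc_a[["interim"]]; b1 <- inc_b[["interim"]]
  r12 <- model$corr["Z1", "Z1_tilde"]
  r13 <- model$corr["Z1", "Z12"]
  d1 <- qnorm(1 - spec$alpha)
  # u1 and d2 are free of delta_tilde, so solve them first, then the
  # (l1, delta_tilde) fixed point
  u1 <- .root(function(u)
    .p2(c(u, d1), c(Inf, Inf), c(0, 0), r12) - a1, .zbracket)
  d2 <- .root(function(d)
    .p2(c(-Inf, d), c(u1, Inf), c(0, 0), r13) - (spec$alpha - a1),
    .zbracket)
  n2 <- spec$n_max / 2
  l1_fun <- function(theta) {
    m12 <- theta * sqrt(c(spec$info_interim,
                          spec$info_interim + spec$info_pipeline) * n2)
    miss <- .p2(c(u1, -Inf), c(Inf, d1), m12, r12)  # stop high, then fail d1
    if (b1 - miss <= 0) return(NA_real_)            # no valid interim spend
    qnorm(b1 - miss) + m12[1L]
  }
  cal <- .calibrate(spec, model, u1, d2, b1, l1_fun)
  if (cal$l1 >= u1)
    stop("RR-GSD solution violates l1 < u1", call. = FALSE)
  out <- list(boundaries = c(l1 = cal$l1, u1 = u1, d1 = d1, d2 = d2),
              alpha1 = a1, beta1 = b1, delta_tilde = cal$theta * spec$sigma)
  out$diagnostics <- .residuals_for(spec, model, out)
  out
}

# defining-equation residuals on the probability scale, recomputed from the
# returned boundary set (solver-independent bookkeeping)
.residuals_for <- function(spec, model, sol) {
  b <- sol$boundaries
  r12 <- model$corr["Z1", "Z1_tilde"]
  r13 <- model$corr["Z1", "Z12"]
  theta <- sol$delta_tilde / spec$sigma
  n2 <- spec$n_max / 2
  m1 <- theta * sqrt(spec$info_interim * n2)
  m2 <- theta * sqrt((spec$info_interim + spec$info_pipeline) * n2)
  m3 <- theta * sqrt(n2)
  res <- switch(spec$design_kind,
    GSD = c(
      u1 = pnorm(b["u1"], lower.tail = FALSE) - sol$alpha1,
      d2 = .p2(c(-Inf, b["d2"]), c(b["u1"], Inf), c(0, 0), r13) -
        (spec$alpha - sol$alpha1),
      l1 = pnorm(b["l1"] - m1) - sol$beta1,
      power = .p2(c(b["l1"], -Inf), c(b["u1"], b["d2"]), c(m1, m3), r13) -
        (spec$beta - sol$beta1)),
    DR_GSD = c(
      u1 = pnorm(b["u1"], lower.tail = FALSE) - sol$alpha1,
      d2 = .p2(c(-Inf, b["d2"]), c(b["u1"], Inf), c(0, 0), r13) -
        (spec$alpha - sol$alpha1),
      l1 = pnorm(b["l1"] - m1) - sol$beta1,
      power = .p2(c(b["l1"], -Inf), c(b["u1"], b["d2"]), c(m1, m3), r13) -
        (spec$beta - sol$beta1),
      d1_balance = .p2(c(b["u1"], -Inf), c(Inf, b["d1"]), c(0, 0), r12) -
        .p2(c(-Inf, b["d1"]), c(b["l1"], Inf), c(0, 0), r12)),
    RR_GSD = c(
      u1 = .p2(c(b["u1"], b["d1"]), c(Inf, Inf), c(0, 0), r12) - sol$alpha1,
      d2 = .p2(c(-Inf, b["d2"]), c(b["u1"], Inf), c(0, 0), r13) -
        (spec$alpha - sol$alpha1),
      l1 = pnorm(b["l1"] - m1) +
        .p2(c(b["u1"], -Inf), c(Inf, b["d1"]), c(m1, m2), r12) - sol$beta1,
      power = .p2(c(b["l1"], -Inf), c(b["u1"], b["d2"]), c(m1, m3), r13) -
        (spec$beta - sol$beta1)))
  names(res) <- sub("\\.(l1|u1|d1|d2)$", "", names(res))
  res
}
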