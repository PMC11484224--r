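#' Global operating characteristics of a solved design
#'
#' Evaluates, analytically under the canonical multivariate normal model, the
#' probability of a futility outcome at interim, of interim rejection, of
#' continuation, the global power, and the expected total sample size at one
#' or more true effect sizes `delta`.
#'
#' The interim outcome probabilities are design-specific:
#' * GSD: futility \eqn{P(Z_1 \le l_1)}, interim rejection
#'   \eqn{P(Z_1 \ge u_1)};
#' * DR-GSD: futility \eqn{P(Z_1 \notin (l_1,u_1), \tilde Z_1 < d_1)} (a
#'   recruitment stop on *either* side followed by non-rejection), interim
#'   rejection \eqn{P(Z_1 \notin (l_1,u_1), \tilde Z_1 \ge d_1)};
#' * RR-GSD: futility \eqn{P(Z_1 \le l_1) + P(Z_1 \ge u_1, \tilde Z_1 < d_1)},
#'   interim rejection \eqn{P(Z_1 \ge u_1, \tilde Z_1 \ge d_1)}.
#'
#' For all three, continuation is \eqn{P(l_1 < Z_1 < u_1)}, global power adds
#' \eqn{P(Z_1 \in (l_1,u_1), Z_{1+2} \ge d_2)} to the interim rejection
#' probability, and the expected total sample size (both arms, pipeline
#' patients always counted) is
#' \eqn{2(\tilde n_1 + P(\mathrm{continue})(n_{max} - \tilde n_1))}.
#'
#' @param object a fitted [drgsd()] design.
#' @param delta true effect size(s), outcome units; defaults to the design's
#'   calibrated alternative, at which power is `1 - beta` by construction.
#' @param ... unused.
#' @return A data frame with one row per `delta` and columns `design`,
#'   `spending_family`, `info_interim`, `info_pipeline`, `delta`,
#'   `p_futility`, `p_reject_interim`, `p_continue`, `power`,
#'   `expected_n_total`.
#' @examples
#' fit <- drgsd("GSD", sigma = 7.5, n_max = 345,
#'              info_interim = 0.29, info_pipeline = 0.3)
#' performance(fit, delta = 1.6)
#' @export
performance <- function(object, delta = NULL, ...) UseMethod("performance")

#' @rdname performance
#' @export
performance.drgsd <- function(object, delta = NULL, ...) {
  if (is.null(delta)) delta <- object$delta_tilde
  spec <- object$spec
  rows <- lapply(delta, function(d) .perf_one(object, d))
  out <- if (length(rows)) do.call(rbind, rows) else .perf_one(object, 0)[0, ]
  k <- nrow(out)
  data.frame(design = rep(spec$design_kind, k),
             spending_family = rep(spec$spending_family, k),
             info_interim = rep(spec$info_interim, k),
             info_pipeline = rep(spec$info_pipeline, k),
             out, row.names = NULL)
}

.perf_one <- function(object, delta) {
  spec <- object$spec
  b <- object$boundaries
  r12 <- object$model$corr["Z1", "Z1_tilde"]
  r13 <- object$model$corr["Z1", "Z12"]
  m <- object$model$drift(delta)
  p_cont <- pnorm(b["u1"] - m[1L]) - pnorm(b["l1"] - m[1L])
  pf_pr <- switch(spec$design_kind,
    GSD = c(pnorm(b["l1"] - m[1L]),
            pnorm(b["u1"] - m[1L], lower.tail = FALSE)),
    DR_GSD = c(
      .p2(c(b["u1"], -Inf), c(Inf, b["d1"]), m[1:2], r12) +
        .p2(c(-Inf, -Inf), c(b["l1"], b["d1"]), m[1:2], r12),
      .p2(c(b["u1"], b["d1"]), c(Inf, Inf), m[1:2], r12) +
        .p2(c(-Inf, b["d1"]), c(b["l1"], Inf), m[1:2], r12)),
    RR_GSD = c(
      pnorm(b["l1"] - m[1L]) +
        .p2(c(b["u1"], -Inf), c(Inf, b["d1"]), m[1:2], r12),
      .p2(c(b["u1"], b["d1"]), c(Inf, Inf), m[1:2], r12)))
  p_final <- .p2(c(b["l1"], b["d2"]), c(b["u1"], Inf), m[c(1L, 3L)], r13)
  s <- object$sizes
  en <- 2 * (s$n1_tilde + p_cont * (s$n_max - s$n1_tilde))
  data.frame(delta = delta,
             p_futility = unname(pf_pr[1L]),
             p_reject_interim = unname(pf_pr[2L]),
             p_continue = unname(p_cont),
             power = unname(pf_pr[2L] + p_final),
             expected_n_total = unname(en))
}

#' Conditional power given continuation
#'
#' Probability of final rejection given that the interim statistic fell in the
#' continuation region:
#' \eqn{CP = P_\delta(Z_{1+2} \ge d_2 \mid Z_1 \in (l_1, u_1))}.
#' Because GSD and DR-GSD share `{l1, u1, d2}`, their conditional power is
#' identical; comparisons with the RR-GSD condition on a different region.
#'
#' @inheritParams performance
#' @param delta true effect size(s), outcome units.
#' @return Conditional power, one value per `delta`.
#' @examples
#' fit <- drgsd("GSD", sigma = 7.5, n_max = 345,
#'              info_interim = 0.29, info_pipeline = 0.3)
#' conditional_power(fit, delta = 1.6)
#' @export
conditional_power <- function(object, delta) {
  stopifnot(inherits(object, "drgsd"))
  vapply(delta, function(d) {
    b <- object$boundaries
    m <- object$model$drift(d)
    r13 <- object$model$corr["Z1", "Z12"]
    p_cont <- pnorm(b["u1"] - m[1L]) - pnorm(b["l1"] - m[1L])
    if (p_cont <= 0)
      stop("conditional power undefined: continuation probability is zero",
           call. = FALSE)
    .p2(c(b["l1"], b["d2"]), c(b["u1"], Inf), m[c(1L, 3L)], r13) / p_cont
  }, numeric(1))
}

#' Evaluate a grid of design scenarios
#'
#' Solves the boundary set and evaluates [performance()] for every combination
#' of spending family, interim and pipeline information fraction, and design
#' kind, at each effect size in `delta`.  The defaults reproduce the standard
#' comparison grid used throughout the package's vignette: `alpha` 0.025,
#' `beta` 0.2, `sigma` 1, `n_max` 200 per arm, interim fractions
#' \{0.3, 0.4, 0.5\}, pipeline fractions \{0.1, 0.2, 0.3\}, both spending
#' families, all three designs.
#'
#' @param info_interim,info_pipeline,spending_family,design_kind vectors of
#'   scenario levels; the full cross product is evaluated.
#' @param delta effect-size grid (outcome units).
#' @param alpha,beta,sigma,n_max scalar design parameters shared by all
#'   scenarios.
#' @return A data frame in fixed column order (`design`, `spending_family`,
#'   `info_interim`, `info_pipeline`, `delta`, `p_futility`,
#'   `p_reject_interim`, `p_continue`, `power`, `expected_n_total`), ordered
#'   by scenario then `delta`, with the solved boundary table attached as
#'   `attr(, "boundaries")` (one row per scenario: `design`,
#'   `spending_family`, `info_interim`, `info_pipeline`, `l1`, `u1`, `d1`,
#'   `d2`, `alpha1`, `beta1`, `delta_tilde`).
#' @examples
#' g <- design_grid(info_interim = 0.4, info_pipeline = 0.2,
#'                  spending_family = "pocock_like", delta = c(0, 0.3))
#' attr(g, "boundaries")
#' @export
design_grid <- function(info_interim = c(0.3, 0.4, 0.5),
                        info_pipeline = c(0.1, 0.2, 0.3),
                        spending_family = c("pocock_like",
                                            "obrien_fleming_like"),
                        design_kind = c("GSD", "DR_GSD", "RR_GSD"),
                        delta = seq(-0.4, 0.8, by = 0.1),
                        alpha = 0.025, beta = 0.2, sigma = 1, n_max = 200) {
  scen <- expand.grid(design_kind = design_kind,
                      spending_family = spending_family,
                      info_interim = info_interim,
                      info_pipeline = info_pipeline,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  perf <- vector("list", nrow(scen))
  bnds <- vector("list", nrow(scen))
  for (i in seq_len(nrow(scen))) {
    s <- scen[i, ]
    fit <- tryCatch(
      drgsd(s$design_kind, alpha, beta, sigma, n_max,
            s$info_interim, s$info_pipeline, s$spending_family),
      error = function(e)
        stop("scenario ", s$design_kind, "/", s$spending_family,
             " I1=", s$info_interim, " Ipipe=", s$info_pipeline, ": ",
             conditionMessage(e), call. = FALSE))
    perf[[i]] <- performance(fit, delta)
    bnds[[i]] <- data.frame(design = s$design_kind,
                            spending_family = s$spending_family,
                            info_interim = s$info_interim,
                            info_pipeline = s$info_pipeline,
                            t(fit$boundaries),
                            alpha1 = fit$alpha1, beta1 = fit$beta1,
                            delta_tilde = fit$delta_tilde, row.names = NULL)
  }
  out <- do.call(rbind, perf)
  if (is.null(out))
    out <- performance(drgsd(spec = design_spec()), numeric(0))[0, ]
  rownames(out) <- NULL
  attr(out, "boundaries") <- do.call(rbind, bnds)
  out
}
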