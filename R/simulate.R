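#' Monte-Carlo validation of a solved design
#'
#' Simulates the trial `nsim` times per replication, `n_reps` replications,
#' and tallies the empirical interim outcome rates, power and expected total
#' sample size.  Two modes:
#'
#' * `"canonical"` — draws \eqn{(Z_1, \tilde Z_1, Z_{1+2})} directly from the
#'   canonical multivariate normal model at drift `delta` and applies the
#'   design's decision logic.  This is the fast route used for operating-
#'   characteristic validation.
#' * `"patient_level"` — generates normally distributed outcomes for every
#'   patient in both arms (control mean 0, intervention mean `delta`, common
#'   `sigma`), computes the stagewise statistics with pooled standard
#'   deviations (so the simulated statistics are t-type, while the boundaries
#'   stay on the normal scale), combines the stages by the pre-fixed
#'   inverse-normal weights, and applies the same decision logic.  Per-arm
#'   counts are rounded to whole patients.
#'
#' Decision logic (nonbinding lower boundary applied by default;
#' `ignore_futility = TRUE` continues recruitment after \eqn{Z_1 \le l_1},
#' the worst case for type-I error):
#' GSD rejects at interim iff \eqn{Z_1 \ge u_1}; DR-GSD stops recruitment when
#' \eqn{Z_1 \notin (l_1,u_1)} and then rejects iff \eqn{\tilde Z_1 \ge d_1};
#' RR-GSD stops the same way but rejects at interim only if \eqn{Z_1 \ge u_1}
#' *and* \eqn{\tilde Z_1 \ge d_1}.  On continuation the final analysis tests
#' \eqn{Z_{1+2} \ge d_2} and the trial uses `n_max` per arm; on an interim
#' stop it uses \eqn{\tilde n_1} per arm (pipeline patients are always
#' recruited).
#'
#' @param object a fitted [drgsd()] design.
#' @param nsim trials per replication.
#' @param seed integer seed; the same seed and configuration reproduce the
#'   result exactly.
#' @param delta true effect size (outcome units); defaults to the calibrated
#'   design alternative.
#' @param n_reps number of independent replications.
#' @param mode `"canonical"` or `"patient_level"`.
#' @param ignore_futility if `TRUE`, the lower boundary is ignored
#'   (recruitment always continues below `u1`).
#' @param ... unused.
#' @return Object of class `"drgsd_sim"`: list with `replications` (data
#'   frame: `rep`, `empirical_power`, `empirical_expected_n`, `p_futility`,
#'   `p_reject_interim`, `p_continue`), the `design` echo, and the simulation
#'   configuration.  `summary()` tabulates mean/variance/quantiles.
#' @examples
#' fit <- drgsd("RR_GSD", info_interim = 0.5, info_pipeline = 0.2,
#'              spending_family = "obrien_fleming_like")
#' sim <- simulate(fit, nsim = 2000, seed = 1, delta = 0.3)
#' summary(sim)
#' @export
simulate.drgsd <- function(object, nsim = 10000, seed = NULL, delta = NULL,
                           n_reps = 1, mode = c("canonical", "patient_level"),
                           ignore_futility = FALSE, ...) {
  mode <- match.arg(mode)
  if (is.null(delta)) delta <- object$delta_tilde
  stopifnot(nsim >= 1, n_reps >= 1, length(delta) == 1L)
  if (!is.null(seed)) set.seed(seed)
  reps <- lapply(seq_len(n_reps), function(r) {
    z <- if (mode == "canonical") .draw_canonical(object, delta, nsim)
         else .draw_patient_level(object, delta, nsim)
    cbind(rep = r, .apply_decisions(object, z, ignore_futility))
  })
  structure(list(replications = as.data.frame(do.call(rbind, reps)),
                 design = object,
                 config = list(nsim = nsim, n_reps = n_reps, seed = seed,
                               delta = delta, mode = mode,
                               ignore_futility = ignore_futility)),
            class = "drgsd_sim")
}

# nsim x 3 matrix of (Z1, Z1_tilde, Z12) from the canonical model
.draw_canonical <- function(object, delta, nsim) {
  ch <- chol(object$model$corr)
  z <- matrix(rnorm(3L * nsim), nsim, 3L) %*% ch
  sweep(z, 2L, object$model$drift(delta), "+")
}

# patient-level generator: outcomes in chunks to bound memory; pooled-SD
# statistics on rounded per-arm counts
.draw_patient_level <- function(object, delta, nsim, chunk = 10000L) {
  spec <- object$spec
  n_max <- round(spec$n_max)
  n1 <- round(spec$info_interim * spec$n_max)
  n1t <- round((spec$info_interim + spec$info_pipeline) * spec$n_max)
  n2 <- n_max - n1                       # post-interim patients per arm
  if (n1 < 2L || n1t < 2L || n2 < 2L || n1t > n_max)
    stop("degenerate per-arm counts after rounding", call. = FALSE)
  w1 <- sqrt(n1 / n_max); w2 <- sqrt(1 - n1 / n_max)
  out <- matrix(NA_real_, nsim, 3L)
  done <- 0L
  while (done < nsim) {
    m <- min(chunk, nsim - done)
    xc <- matrix(rnorm(n_max * m, 0, spec$sigma), n_max, m)
    xi <- matrix(rnorm(n_max * m, delta, spec$sigma), n_max, m)
    z1 <- .two_sample_z(xi[seq_len(n1), , drop = FALSE],
                        xc[seq_len(n1), , drop = FALSE])
    z1t <- .two_sample_z(xi[seq_len(n1t), , drop = FALSE],
                         xc[seq_len(n1t), , drop = FALSE])
    z2 <- .two_sample_z(xi[(n1 + 1L):n_max, , drop = FALSE],
                        xc[(n1 + 1L):n_max, , drop = FALSE])
    out[done + seq_len(m), ] <- cbind(z1, z1t, w1 * z1 + w2 * z2)
    done <- done + m
  }
  out
}

# columnwise two-sample z/t statistic with pooled SD: rows = patients
.two_sample_z <- function(xi, xc) {
  n <- nrow(xi)
  mi <- colMeans(xi); mc <- colMeans(xc)
  ssi <- colSums(xi^2) - n * mi^2
  ssc <- colSums(xc^2) - n * mc^2
  s_pool <- sqrt((ssi + ssc) / (2 * n - 2))
  (mi - mc) / s_pool * sqrt(n / 2)
}

# per-replication tallies from an nsim x 3 statistic matrix
.apply_decisions <- function(object, z, ignore_futility = FALSE) {
  b <- object$boundaries
  kind <- object$spec$design_kind
  low <- if (ignore_futility) rep(FALSE, nrow(z)) else z[, 1L] <= b[["l1"]]
  high <- z[, 1L] >= b[["u1"]]
  stop_rec <- low | high
  if (kind == "GSD") {
    rej_int <- high
    fut <- low
  } else if (kind == "DR_GSD") {
    rej_int <- stop_rec & z[, 2L] >= b[["d1"]]
    fut <- stop_rec & !rej_int
  } else {
    rej_int <- high & z[, 2L] >= b[["d1"]]
    fut <- stop_rec & !rej_int
  }
  cont <- !stop_rec
  rej <- rej_int | (cont & z[, 3L] >= b[["d2"]])
  s <- object$sizes
  n_trial <- 2 * ifelse(cont, s$n_max, s$n1_tilde)
  data.frame(empirical_power = mean(rej),
             empirical_expected_n = mean(n_trial),
             p_futility = mean(fut),
             p_reject_interim = mean(rej_int),
             p_continue = mean(cont))
}

#' @export
print.drgsd_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Monte-Carlo run: %s design, mode = %s, delta = %g\n",
              x$design$spec$design_kind, cfg$mode, cfg$delta))
  cat(sprintf("  %d replication(s) x %d trials%s\n", cfg$n_reps, cfg$nsim,
              if (!is.null(cfg$seed)) sprintf(", seed %d", cfg$seed) else ""))
  print(summary(x))
  invisible(x)
}

#' Summarize a Monte-Carlo run
#'
#' Mean, variance and quartiles of the per-replication empirical power and
#' expected total sample size.  With a single replication the variance is
#' reported as `NA` (zero degrees of freedom).
#'
#' @param object a `"drgsd_sim"` result.
#' @param ... unused.
#' @return Data frame with one row per metric.
#' @export
summary.drgsd_sim <- function(object, ...) {
  r <- object$replications
  if (nrow(r) == 0L) stop("empty simulation result", call. = FALSE)
  one <- function(v) {
    q <- quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(mean = mean(v),
               variance = if (length(v) > 1L) var(v) else NA_real_,
               min = q[1L], q25 = q[2L], median = q[3L], q75 = q[4L],
               max = q[5L])
  }
  out <- rbind(one(r$empirical_power), one(r$empirical_expected_n))
  data.frame(metric = c("empirical_power", "empirical_expected_n"), out,
             row.names = NULL)
}
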