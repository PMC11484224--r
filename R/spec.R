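#' Specify a two-stage delayed-response trial design problem
#'
#' Collects and validates the parameters that define a two-stage
#' group-sequential design with (possibly) delayed responses: one-sided error
#' levels, outcome standard deviation, the maximum per-arm sample size, and the
#' interim and pipeline information fractions.  The information fraction
#' `info_interim` is the proportion of `n_max` observed per arm at the interim
#' look; `info_pipeline` is the additional proportion already recruited but not
#' yet observed because of the response delay.
#'
#' @param alpha one-sided type-I error level.
#' @param beta type-II error level (design power is `1 - beta`).
#' @param sigma common outcome standard deviation (> 0).
#' @param n_max maximum per-arm sample size.
#' @param info_interim interim information fraction in (0, 1).
#' @param info_pipeline pipeline information fraction; must be strictly
#'   positive for the delayed-response designs and satisfy
#'   `info_interim + info_pipeline < 1` (a design that waits for all pipeline
#'   data to arrive before deciding is a different design entirely).
#' @param spending_family `"pocock_like"` or `"obrien_fleming_like"` (several
#'   common aliases such as `"pocock"` and `"obf"` are accepted).
#' @param design_kind `"GSD"`, `"DR_GSD"` or `"RR_GSD"` (aliases with `-`
#'   accepted).
#'
#' @return An object of class `"drgsd_spec"`: a validated list with the
#'   canonical field names above.
#' @seealso [drgsd()] which solves the boundaries for a spec,
#'   [sample_size_plan()], [canonical_model()].
#' @examples
#' design_spec(info_interim = 0.29, info_pipeline = 0.3,
#'             sigma = 7.5, n_max = 345, design_kind = "DR_GSD")
#' @export
design_spec <- function(alpha = 0.025, beta = 0.2, sigma = 1, n_max = 200,
                        info_interim = 0.5, info_pipeline = 0,
                        spending_family = "pocock_like",
                        design_kind = "GSD") {
  spending_family <- match_spending(spending_family)
  design_kind <- match_kind(design_kind)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            is.numeric(beta), length(beta) == 1L, beta > 0, beta < 1,
            is.numeric(sigma), length(sigma) == 1L, sigma > 0,
            is.numeric(n_max), length(n_max) == 1L, n_max > 0,
            is.numeric(info_interim), length(info_interim) == 1L,
            is.numeric(info_pipeline), length(info_pipeline) == 1L)
  if (info_interim <= 0 || info_interim >= 1)
    stop("'info_interim' must lie strictly between 0 and 1", call. = FALSE)
  if (info_pipeline < 0)
    stop("'info_pipeline' must be non-negative", call. = FALSE)
  if (info_interim + info_pipeline >= 1)
    stop("invalid design: info_interim + info_pipeline must be < 1 ",
         "(offending keys: info_interim, info_pipeline)", call. = FALSE)
  if (design_kind %in% c("DR_GSD", "RR_GSD") && info_pipeline <= 0)
    stop("design_kind '", design_kind,
         "' requires a positive pipeline information fraction", call. = FALSE)
  structure(
    list(alpha = alpha, beta = beta, sigma = sigma, n_max = n_max,
         info_interim = info_interim, info_pipeline = info_pipeline,
         spending_family = spending_family, design_kind = design_kind),
    class = "drgsd_spec")
}

match_spending <- function(x) {
  x <- tolower(gsub("[ '’-]", "_", as.character(x)[1L]))
  if (x %in% c("pocock", "pocock_like", "p")) return("pocock_like")
  if (x %in% c("obf", "obf_like", "obrien_fleming", "obrien_fleming_like",
               "o_brien_fleming", "o_brien_fleming_like", "of"))
    return("obrien_fleming_like")
  stop("unknown spending family: ", x, call. = FALSE)
}

match_kind <- function(x) {
  x <- toupper(gsub("-", "_", as.character(x)[1L]))
  if (!x %in% .design_kinds)
    stop("unknown design kind: ", x, " (expected one of ",
         paste(.design_kinds, collapse = ", "), ")", call. = FALSE)
  x
}

#' @export
print.drgsd_spec <- function(x, ...) {
  cat("Two-stage design specification (", x$design_kind, ")\n", sep = "")
  cat(sprintf("  alpha = %g (one-sided), beta = %g, sigma = %g\n",
              x$alpha, x$beta, x$sigma))
  cat(sprintf("  n_max = %g per arm; I1 = %g, I_pipeline = %g; spending: %s\n",
              x$n_max, x$info_interim, x$info_pipeline, x$spending_family))
  invisible(x)
}

#' Per-arm sample sizes implied by the information fractions
#'
#' Derives the per-arm interim count `n1 = I1 * n_max`, the pipeline count,
#' the decision-analysis count `n1_tilde = n1 + n_pipeline`, and the number of
#' additionally recruited patients on continuation `n_max - n1_tilde`.  All
#' values are kept real-valued; rounding to whole patients is a reporting
#' concern (`round = TRUE` rounds to nearest).
#'
#' @param spec a [design_spec()] (or an object carrying one).
#' @param round round per-arm counts to whole patients for display.
#' @return A list with per-arm components `n1`, `n_pipeline`, `n1_tilde`,
#'   `n2_continue`, `n_max` and a `totals` vector (both arms combined).
#' @examples
#' sample_size_plan(design_spec(info_interim = 0.29, info_pipeline = 0.3,
#'                              n_max = 345))
#' @export
sample_size_plan <- function(spec, round = FALSE) {
  spec <- as_spec(spec)
  n1 <- spec$info_interim * spec$n_max
  npipe <- spec$info_pipeline * spec$n_max
  n1t <- n1 + npipe
  n2 <- spec$n_max - n1t
  if (round) {
    n1 <- round(n1); npipe <- round(npipe)
    n1t <- round(n1t); n2 <- round(spec$n_max) - n1t
  }
  out <- list(n1 = n1, n_pipeline = npipe, n1_tilde = n1t, n2_continue = n2,
              n_max = if (round) round(spec$n_max) else spec$n_max)
  out$totals <- 2 * c(n1 = out$n1, n_pipeline = out$n_pipeline,
                      n1_tilde = out$n1_tilde, n2_continue = out$n2_continue,
                      n_max = out$n_max)
  out
}

as_spec <- function(x) {
  if (inherits(x, "drgsd_spec")) return(x)
  if (inherits(x, "drgsd") && inherits(x$spec, "drgsd_spec")) return(x$spec)
  stop("expected a 'drgsd_spec' or fitted 'drgsd' object", call. = FALSE)
}

#' Fixed (single-stage) design sample size
#'
#' Per-group sample size of the classical single-stage two-arm z-test,
#' \deqn{n = 2 (z_{1-\alpha} + z_{1-\beta})^2 (\sigma/\delta)^2.}
#'
#' @param alpha one-sided type-I error level.
#' @param beta type-II error level.
#' @param delta assumed treatment effect (non-zero).
#' @param sigma common standard deviation.
#' @param round round up to whole patients.
#' @return Per-group sample size (real-valued unless `round = TRUE`).
#' @examples
#' fixed_design_n(0.025, 0.2, delta = 1.6, sigma = 7.5)  # ~345 per group
#' @export
fixed_design_n <- function(alpha, beta, delta, sigma, round = FALSE) {
  if (!is.numeric(delta) || any(delta == 0))
    stop("'delta' must be non-zero", call. = FALSE)
  n <- 2 * (qnorm(1 - alpha) + qnorm(1 - beta))^2 * (sigma / delta)^2
  if (round) ceiling(n) else n
}
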