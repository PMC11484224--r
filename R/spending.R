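#' Error-spending functions
#'
#' Cumulative type-I or type-II error spent by information fraction `t`, using
#' the Lan-DeMets spending functions that mimic the Pocock and O'Brien-Fleming
#' group-sequential boundaries:
#' \deqn{f_P(t) = \ell \,\log(1 + (e - 1)\,t)}
#' \deqn{f_{OBF}(t) = 2\left(1 - \Phi\!\big(\Phi^{-1}(1 - \ell/2)/\sqrt{t}\big)\right)}
#' where \eqn{\ell} is the total level to spend.  Both start at 0, are
#' nondecreasing, and reach \eqn{\ell} at `t = 1` (the O'Brien-Fleming form up
#' to floating-point rounding).  The same families are used for alpha- and
#' beta-spending; only the level differs.
#'
#' @param t information fraction(s) in \[0, 1\]; vectorized.
#' @param level total error level to spend over the trial.
#' @param family `"pocock_like"` or `"obrien_fleming_like"`.
#' @return Cumulative error spent at each `t`.
#' @references Lan, K.K.G. and DeMets, D.L. (1983). Discrete sequential
#'   boundaries for clinical trials. *Biometrika* 70, 659-663.
#' @examples
#' error_spend(0.29, 0.025, "pocock_like")           # interim alpha spend
#' qnorm(1 - error_spend(0.29, 0.025, "pocock_like")) # interim efficacy bound
#' @export
error_spend <- function(t, level, family = c("pocock_like",
                                             "obrien_fleming_like")) {
  family <- match_spending(family[1L])
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  if (any(t < 0 | t > 1)) stop("'t' must lie in [0, 1]", call. = FALSE)
  out <- switch(family,
    pocock_like = level * log(1 + (exp(1) - 1) * t),
    obrien_fleming_like = {
      s <- numeric(length(t))
      pos <- t > 0
      s[pos] <- 2 * pnorm(qnorm(1 - level / 2) / sqrt(t[pos]),
                          lower.tail = FALSE)
      s
    })
  pmin(out, level)
}

#' Stage-wise error-spending increments
#'
#' Splits a total error level into the amount spent at the interim analysis,
#' `f(t1)`, and the remainder `level - f(t1)` left for the final analysis.
#' A design needs both increments strictly positive; a degenerate split (all
#' error gone at interim) is an error.
#'
#' @inheritParams error_spend
#' @param t1 interim information fraction, strictly inside (0, 1).
#' @return Named numeric vector `c(interim = , final = )`.
#' @examples
#' spend_increments(0.29, 0.025, "pocock_like")
#' @export
spend_increments <- function(t1, level, family = "pocock_like") {
  if (t1 <= 0 || t1 >= 1)
    stop("'t1' must lie strictly between 0 and 1", call. = FALSE)
  s1 <- error_spend(t1, level, family)
  s2 <- level - s1
  if (s1 <= 0 || s2 <= 0)
    stop("degenerate error spend: both stage increments must be positive ",
         sprintf("(interim %.3g, final %.3g)", s1, s2), call. = FALSE)
  c(interim = s1, final = s2)
}
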