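# Shared fixtures: the schizophrenia-trial worked example (effect 1.6, SD 7.5,
# 345 per arm, interim at 29% information, 30% in the pipeline, Pocock-like
# spending), solved once per test run.
ex_args <- list(alpha = 0.025, beta = 0.2, sigma = 7.5, n_max = 345,
                info_interim = 0.29, info_pipeline = 0.3,
                spending_family = "pocock_like")
ex_fit <- function(kind) do.call(drgsd, c(list(design_kind = kind), ex_args))
ex_gsd <- ex_fit("GSD")
ex_dr <- ex_fit("DR_GSD")
ex_rr <- ex_fit("RR_GSD")

# Independent Monte-Carlo oracle for the canonical statistics: constructs
# (Z1, Z1~, Z12) from Brownian-motion score increments (a different route
# than the package's Cholesky-based simulator), with drift theta = delta/sigma.
oracle_draw <- function(n, info2, theta, n_max) {
  t <- c(info2, 1)
  i1 <- rnorm(n, 0, sqrt(t[1L]))
  i2 <- rnorm(n, 0, sqrt(t[2L] - t[1L]))
  i3 <- rnorm(n, 0, sqrt(1 - t[2L]))
  s <- cbind(i1, i1 + i2, i1 + i2 + i3)
  sweep(sweep(s, 2L, sqrt(t), "/"), 2L, theta * sqrt(t * n_max / 2), "+")
}

oracle_draw_for <- function(fit, delta, n) {
  oracle_draw(n, fit$model$info[1:2], delta / fit$spec$sigma, fit$spec$n_max)
}

# 3-standard-error tolerance for a binomial proportion estimated from n draws
mc_tol <- function(p, n) 3 * sqrt(p * (1 - p) / n)
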