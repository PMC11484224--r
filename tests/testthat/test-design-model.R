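test_that("sample size plan follows the information fractions", {
  # worked example: 200 observed + 208 pipeline of 690 -> 408 at decision
  p <- sample_size_plan(design_spec(info_interim = 0.29, info_pipeline = 0.3,
                                    n_max = 345))
  expect_equal(unname(p$totals[c("n1", "n_pipeline", "n1_tilde")]),
               c(200.1, 207, 407.1), tolerance = 1e-9)
  expect_equal(round(unname(p$totals["n1_tilde"])), 407)  # real-valued core
  # zero-pipeline case
  p0 <- sample_size_plan(design_spec(info_interim = 0.5, info_pipeline = 0,
                                     n_max = 200))
  expect_equal(unname(unlist(p0[c("n1", "n_pipeline", "n1_tilde",
                                  "n2_continue")])), c(100, 0, 100, 100))
  # additivity n1 + pipeline
  p3 <- sample_size_plan(design_spec(info_interim = 0.3, info_pipeline = 0.3,
                                     n_max = 200))
  expect_equal(p3$n1_tilde, 120)
  expect_equal(unname(p3$totals["n1_tilde"]), 240)
  # partition identity
  expect_equal(p$n1 + p$n_pipeline + p$n2_continue, p$n_max)
})

test_that("spec validation rejects impossible designs", {
  expect_error(design_spec(info_interim = 0.6, info_pipeline = 0.5),
               "info_interim, info_pipeline")
  expect_error(design_spec(info_interim = 0.3, info_pipeline = 0,
                           design_kind = "DR_GSD"), "pipeline")
  expect_error(design_spec(alpha = 0), "alpha")
  expect_error(design_spec(spending_family = "hsd"), "unknown spending")
})

test_that("canonical correlation structure is sqrt(Ia/Ib)", {
  m <- canonical_model(design_spec(info_interim = 0.29, info_pipeline = 0.3))
  expect_equal(m$corr["Z1", "Z1_tilde"], sqrt(0.29 / 0.59), tolerance = 1e-12)
  expect_equal(m$corr["Z1", "Z12"], sqrt(0.29), tolerance = 1e-12)
  expect_equal(m$corr["Z1_tilde", "Z12"], sqrt(0.59), tolerance = 1e-12)
  expect_equal(m$corr["Z1", "Z1_tilde"], 0.7011, tolerance = 1e-4)
  expect_equal(unname(diag(m$corr)), rep(1, 3))
  # no pipeline: Z1~ is Z1
  m0 <- canonical_model(design_spec(info_interim = 0.4, info_pipeline = 0))
  expect_equal(m0$corr["Z1", "Z1_tilde"], 1, tolerance = 1e-12)
})

test_that("pairwise correlations obey the independent-increments product rule", {
  set.seed(42)
  for (i in 1:25) {
    t1 <- runif(1, 0.05, 0.9)
    dt <- runif(1, 0, 0.99 - t1)
    m <- canonical_model(design_spec(info_interim = t1, info_pipeline = dt))
    expect_equal(m$corr["Z1", "Z12"],
                 m$corr["Z1", "Z1_tilde"] * m$corr["Z1_tilde", "Z12"],
                 tolerance = 1e-12)
    expect_true(all(eigen(m$corr, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-12))
  }
})

test_that("drift is linear and matches the closed form at the final analysis", {
  spec <- design_spec(sigma = 7.5, n_max = 345, info_interim = 0.29,
                      info_pipeline = 0.3)
  m <- canonical_model(spec)
  expect_equal(m$drift(0), c(Z1 = 0, Z1_tilde = 0, Z12 = 0))
  expect_equal(m$drift(3.2), 2 * m$drift(1.6), tolerance = 1e-12)
  expect_equal(unname(m$drift(1.6)["Z12"]), (1.6 / 7.5) * sqrt(345 / 2),
               tolerance = 1e-12)
  expect_equal(sum(m$weights^2), 1, tolerance = 1e-12)
})

test_that("mvn_rect_prob matches closed forms in low dimensions", {
  expect_equal(mvn_rect_prob(-Inf, 1.96), 0.975, tolerance = 1e-4)
  expect_equal(mvn_rect_prob(-Inf, qnorm(0.975)), 0.975, tolerance = 1e-12)
  # independence factorization
  expect_equal(mvn_rect_prob(c(-1, 0), c(1, 2), corr = diag(2)),
               (pnorm(1) - pnorm(-1)) * (pnorm(2) - pnorm(0)),
               tolerance = 1e-9)
  # a rectangle unconstrained in two coordinates is a 1-D marginal
  co <- canonical_model(design_spec(info_interim = 0.29,
                                    info_pipeline = 0.3))$corr
  expect_equal(mvn_rect_prob(c(0.259, -Inf, -Inf), c(2.322, Inf, Inf),
                             mean = rep(0, 3), corr = co),
               pnorm(2.322) - pnorm(0.259), tolerance = 1e-7)
})

test_that("mvn_rect_prob agrees with a brute-force Monte-Carlo oracle", {
  co <- canonical_model(design_spec(info_interim = 0.29,
                                    info_pipeline = 0.3))$corr
  set.seed(7)
  z <- oracle_draw(1e6, c(0.29, 0.59), 0, 1)
  lo <- c(0.2, -0.5, 0.1); hi <- c(2.3, 1.8, Inf)
  inside <- z[, 1] > lo[1] & z[, 1] < hi[1] &
            z[, 2] > lo[2] & z[, 2] < hi[2] & z[, 3] > lo[3]
  p_hat <- mean(inside)
  p <- mvn_rect_prob(lo, hi, rep(0, 3), co)
  expect_lt(abs(p - p_hat), mc_tol(p, 1e6))
})

test_that("mvn_rect_prob validates its inputs", {
  expect_error(mvn_rect_prob(1, 0), "below")
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(mvn_rect_prob(c(-1, -1), c(1, 1), corr = bad),
               "positive semi-definite")
  expect_error(mvn_rect_prob(rep(0, 4), rep(1, 4)), "between 1 and 3")
})
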