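# The published worked example (effect 1.6, SD 7.5, 345/arm, I1 = 0.29,
# pipeline 0.3, Pocock-like spending) prints its boundary sets to 3 decimals;
# unit tolerance 1e-3 covers the printed rounding.

test_that("GSD boundaries reproduce the worked example", {
  b <- coef(ex_gsd)
  expect_equal(unname(b[c("l1", "u1", "d2")]), c(0.259, 2.322, 2.119),
               tolerance = 1e-3)
  expect_true(is.na(b["d1"]))
  # alpha-spending partition: interim + final rejection exhausts alpha
  a_total <- pnorm(b[["u1"]], lower.tail = FALSE) +
    mvn_rect_prob(c(-Inf, b[["d2"]]), c(b[["u1"]], Inf), c(0, 0),
                  ex_gsd$model$corr[c(1, 3), c(1, 3)])
  expect_equal(a_total, 0.025, tolerance = 1e-7)
})

test_that("calibrated design alternative restores the target power", {
  # GSD and RR-GSD: total type-II error at delta~ is beta by construction.
  # DR-GSD inherits the GSD's {l1, u1, d2, delta~}; its balance equation
  # converts some futility mass into interim rejections under positive drift,
  # so its power at delta~ lies slightly *above* 1 - beta.
  for (fit in list(ex_gsd, ex_rr))
    expect_lt(abs(performance(fit, fit$delta_tilde)$power - 0.8), 1e-6)
  p_dr <- performance(ex_dr, ex_dr$delta_tilde)$power
  expect_gte(p_dr, 0.8 - 1e-9)
  expect_lt(p_dr - 0.8, 0.05)
  for (fit in list(ex_gsd, ex_dr, ex_rr)) {
    # a two-stage design at the same n_max needs a larger effect than the
    # fixed design powered at delta = 1.6
    expect_gt(fit$delta_tilde, 1.6)
  }
  # inversion oracle: l1 must equal the beta1-quantile shifted by the drift
  th <- ex_gsd$delta_tilde / 7.5
  expect_equal(coef(ex_gsd)[["l1"]],
               qnorm(ex_gsd$beta1) + th * sqrt(0.29 * 345 / 2),
               tolerance = 1e-9)
  expect_lt(abs(th - 0.235), 1e-3)
})

test_that("DR-GSD shares the GSD continuation set and balances d1", {
  expect_identical(coef(ex_gsd)[c("l1", "u1", "d2")],
                   coef(ex_dr)[c("l1", "u1", "d2")])
  expect_identical(ex_gsd$delta_tilde, ex_dr$delta_tilde)
  b <- coef(ex_dr)
  expect_equal(b[["d1"]], 1.584, tolerance = 1e-3)
  r12 <- ex_dr$model$corr["Z1", "Z1_tilde"]
  co <- matrix(c(1, r12, r12, 1), 2)
  bal <- mvn_rect_prob(c(b[["u1"]], -Inf), c(Inf, b[["d1"]]), c(0, 0), co) -
    mvn_rect_prob(c(-Inf, b[["d1"]]), c(b[["l1"]], Inf), c(0, 0), co)
  expect_lt(abs(bal), 1e-7)
})

test_that("DR-GSD nonbinding type-I inequality chain holds", {
  b <- coef(ex_dr)
  r12 <- ex_dr$model$corr["Z1", "Z1_tilde"]
  co <- matrix(c(1, r12, r12, 1), 2)
  # interim rejection with futility respected ...
  p_respect <- mvn_rect_prob(c(b[["u1"]], b[["d1"]]), c(Inf, Inf),
                             c(0, 0), co) +
    mvn_rect_prob(c(-Inf, b[["d1"]]), c(b[["l1"]], Inf), c(0, 0), co)
  # ... and with the lower boundary ignored entirely
  p_ignore <- mvn_rect_prob(c(b[["u1"]], b[["d1"]]), c(Inf, Inf), c(0, 0), co)
  expect_lte(p_ignore, p_respect + 1e-12)
  expect_lte(p_respect, ex_dr$alpha1 + 1e-7)
  # total null rejection in both regimes stays at or below alpha
  r13 <- ex_dr$model$corr["Z1", "Z12"]
  co13 <- matrix(c(1, r13, r13, 1), 2)
  p_final <- mvn_rect_prob(c(b[["l1"]], b[["d2"]]), c(b[["u1"]], Inf),
                           c(0, 0), co13)
  p_final_ignore <- mvn_rect_prob(c(-Inf, b[["d2"]]), c(b[["u1"]], Inf),
                                  c(0, 0), co13)
  expect_lte(p_respect + p_final, 0.025 + 1e-7)
  expect_lte(p_ignore + p_final_ignore, 0.025 + 1e-7)
})

test_that("RR-GSD boundaries reproduce the worked example and its constraints", {
  b <- coef(ex_rr)
  expect_equal(unname(b), c(-0.164, 1.815, 1.960, 2.043), tolerance = 1e-3)
  # d1 is fixed by construction, independent of everything else
  expect_identical(b[["d1"]], qnorm(1 - 0.025))
  expect_identical(coef(drgsd("RR_GSD", info_interim = 0.4,
                              info_pipeline = 0.1))[["d1"]],
                   qnorm(1 - 0.025))
  expect_lt(b[["l1"]], b[["u1"]])
  expect_true(all(abs(residuals(ex_rr)) <= 1e-6))
})

test_that("solved constraints agree with a brute-force Monte-Carlo oracle", {
  set.seed(11)
  z <- oracle_draw_for(ex_rr, 0, 4e5)
  b <- coef(ex_rr)
  n <- nrow(z)
  # interim alpha spend: P0(Z1 >= u1, Z1~ >= d1) = alpha1
  p1 <- mean(z[, 1] >= b[["u1"]] & z[, 2] >= b[["d1"]])
  expect_lt(abs(p1 - ex_rr$alpha1), mc_tol(ex_rr$alpha1, n))
  # final alpha spend: P0(Z1 < u1, Z12 >= d2) = alpha - alpha1
  p2 <- mean(z[, 1] < b[["u1"]] & z[, 3] >= b[["d2"]])
  expect_lt(abs(p2 - (0.025 - ex_rr$alpha1)), mc_tol(0.015, n))
  # interim beta spend at the calibrated alternative
  za <- oracle_draw_for(ex_rr, ex_rr$delta_tilde, 4e5)
  p3 <- mean(za[, 1] <= b[["l1"]] |
             (za[, 1] >= b[["u1"]] & za[, 2] < b[["d1"]]))
  expect_lt(abs(p3 - ex_rr$beta1), mc_tol(ex_rr$beta1, n))
})

test_that("boundary monotonicity in the spending and pipeline parameters", {
  # earlier/larger interim alpha spend lowers the interim efficacy boundary
  u1 <- vapply(c(0.2, 0.35, 0.5, 0.65),
               function(t) coef(drgsd("GSD", info_interim = t))[["u1"]],
               numeric(1))
  expect_true(all(diff(u1) < 0))
  # more pipeline information raises the DR-GSD decision value
  d1 <- vapply(c(0.1, 0.2, 0.3, 0.4),
               function(dt) coef(drgsd("DR_GSD", info_interim = 0.3,
                                       info_pipeline = dt))[["d1"]],
               numeric(1))
  expect_true(all(diff(d1) > 0))
})

test_that("every solver reports defining-equation residuals below 1e-6", {
  for (fit in list(ex_gsd, ex_dr, ex_rr)) {
    expect_true(all(abs(residuals(fit)) <= 1e-6))
    expect_lt(fit$alpha1, fit$spec$alpha)
    expect_lt(fit$beta1, fit$spec$beta)
  }
})
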