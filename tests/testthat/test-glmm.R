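test_that("natural spline basis spans linear functions and is smooth at knots", {
  t <- rep(1:24, 3)
  B <- natural_spline_basis(t, 2)
  expect_equal(ncol(B), 2L)
  # least-squares residual of t on [1, B] is zero: the basis spans linears
  res <- resid(lm(t ~ B))
  expect_lt(max(abs(res)), 1e-8)
  B8 <- natural_spline_basis(t, 8)
  expect_equal(ncol(B8), 8L)
  expect_equal(nrow(B8), length(t))

  # second derivative continuous at interior knots (finite differences on a
  # fine grid: the centered second difference has no jumps)
  tg <- seq(1, 24, by = 0.001)
  Bg <- splines::ns(tg, df = 8)
  for (j in 1:8) {
    d2 <- diff(Bg[, j], differences = 2) / 0.001^2
    expect_lt(max(abs(diff(d2))), 0.5)  # jump in f'' would be O(1/h) ~ 1e3
  }
  # linearity beyond the boundary knots: f'' = 0 outside the range
  tout <- seq(25, 30, by = 0.01)
  Bo <- predict(splines::ns(1:24, df = 4), tout)
  for (j in 1:4) {
    d2 <- diff(Bo[, j], differences = 2)
    expect_lt(max(abs(d2)), 1e-8)
  }

  expect_equal(ncol(natural_spline_basis(t, 0)), 0L)
  expect_error(natural_spline_basis(t, 1), "v = 1")
  expect_error(natural_spline_basis(rep(3, 10), 2), "constant")
})

test_that("null model recovery: theta near 0 and variances near 0", {
  pan <- simulate_panel(desk_design(),
                        params = sim_params(theta = 0, var_village = 0,
                                            var_child = 0,
                                            mean_children_per_sector = 12),
                        seed = 61)
  f <- fit_alri_glmm(pan, v = 2)
  expect_true(f$converged)
  expect_lt(abs(f$theta_hat), 2 * f$se_model)
  expect_lt(f$var_village_hat, 0.02)
  expect_lt(f$var_child_hat, 0.03)
  expect_s3_class(f, "alri_fit")
  expect_named(coef(f)[1:2], c("(Intercept)", "x"))
  ci <- confint(f)
  expect_lt(ci[1], f$theta_hat); expect_gt(ci[2], f$theta_hat)
})

test_that("Laplace engines and the adaptive-quadrature audit fitter agree", {
  pan <- desk_panel(theta = -0.2, seed = 62)
  f_tmb <- fit_alri_glmm(pan, v = 0, engine = "glmmTMB")
  f_lme <- fit_alri_glmm(pan, v = 0, engine = "glmer")
  expect_lt(abs(f_tmb$theta_hat - f_lme$theta_hat), 0.01)
  agq <- fit_alri_glmm_agq(pan, v = 0, nq = 15)
  expect_true(agq$converged)
  expect_lt(abs(agq$theta_hat - f_tmb$theta_hat), 0.01)
  # independent quadrature evaluation reproduces the engine log-likelihood
  ll <- sum(stovesim:::fit_cluster_logliks(f_tmb, f_tmb$beta, nq = 15))
  expect_equal(ll, f_tmb$loglik, tolerance = 1e-3)
})

test_that("cluster-robust sandwich behaves under correct and broken correlation models", {
  # correctly specified: robust and model SEs comparable; score near zero
  ratios <- vapply(1:6, function(r) {
    pan <- desk_panel(theta = -0.1, mean_children = 8, seed = 70 + r)
    f <- robust_variance(fit_alri_glmm(pan, v = 2), nq = 10)
    expect_lt(f$score_norm, 1)
    f$robust_ratio
  }, numeric(1))
  expect_gt(mean(ratios), 0.7)
  expect_lt(mean(ratios), 1.35)

  # induced extra within-cluster correlation (shared sector-period shocks the
  # model does not know about) inflates the robust SE relative to model SE
  ratios2 <- vapply(1:4, function(r) {
    set.seed(80 + r)
    pan <- desk_panel(theta = 0, mean_children = 8, seed = 90 + r)
    shock <- matrix(rnorm(12 * 24, 0, 0.8), 12, 24)
    pr <- plogis(qlogis(1 / 12) + shock[cbind(pan$sector, pan$period)])
    pan$y <- rbinom(nrow(pan), 1, pr)
    f <- robust_variance(fit_alri_glmm(pan, v = 2), nq = 10)
    f$robust_ratio
  }, numeric(1))
  expect_gt(mean(ratios2), 1)

  # single cluster: sandwich undefined
  pan1 <- desk_panel(seed = 99)
  pan1$sector <- 1; pan1$group <- 1
  pan1$x <- as.integer(pan1$period > 12)
  f1 <- fit_alri_glmm(pan1, v = 0)
  expect_error(robust_variance(f1), "single cluster")
})

test_that("spline-sensitivity table is stable without a trend and guards rank deficiency", {
  pan <- desk_panel(theta = -0.2, mean_children = 10, seed = 64)
  tab <- sensitivity_over_v(pan, v_list = c(4, 6, 8))
  expect_equal(tab$v, c(4, 6, 8))
  expect_true(all(tab$converged))
  # no-trend data: theta varies across v by less than its SE
  expect_lt(max(tab$theta_hat) - min(tab$theta_hat), min(tab$se_model))
  # v too large for the number of distinct periods is omitted with a warning
  short <- pan[pan$period <= 8, ]
  short$x <- as.integer(short$period > 4)
  expect_warning(tab2 <- sensitivity_over_v(short, v_list = c(4, 12)),
                 "rank-deficient")
  expect_equal(tab2$v, 4)
})

test_that("birthweight models use the strict LBW cut and recover effects", {
  bw <- simulate_birthweights(60, 25, effect_g = -100,
                              treated = rep(c(TRUE, FALSE), 30), seed = 55)
  fc <- fit_birthweight(bw, "continuous")
  expect_lt(abs(fc$effect - (-100)), 2 * fc$se_model)
  expect_gt(fc$se_robust, 0)
  # ICC estimate consistent with the generator at moderate size
  expect_lt(abs(fc$icc_hat - 0.03357), 0.04)

  # strict cut: 2499 g is LBW, 2500 g is not
  bw2 <- bw
  bw2$weight <- rep(c(2499, 2500, 2500, 2500), length.out = nrow(bw2))
  fb <- fit_birthweight(bw2, "lbw")
  expect_equal(fb$lbw_rate, mean(rep(c(2499, 2500, 2500, 2500),
                                     length.out = nrow(bw2)) == 2499))
  fl <- fit_birthweight(bw, "lbw")
  expect_true(is.finite(fl$effect))
  expect_gt(fl$se_robust, 0)
  expect_error(fit_birthweight(bw[bw$treated, ], "continuous"), "2 clusters")
})
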