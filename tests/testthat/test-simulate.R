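test_that("seasonal multiplier has the stated amplitude and unit geometric mean", {
  p1 <- sim_params(season_amplitude = 1)
  expect_equal(seasonal_multiplier(1:24, p1), rep(1, 24))
  p <- sim_params()
  expect_equal(seasonal_multiplier(3, p), 1.05)        # peak month
  expect_equal(seasonal_multiplier(9, p), 1 / 1.05)    # trough month
  # log-symmetry: geometric mean over one full cycle is 1
  gm <- exp(mean(log(seasonal_multiplier(seq(0, 12, length.out = 1201)[-1], p))))
  expect_equal(gm, 1, tolerance = 1e-6)
  expect_error(sim_params(season_period = 0), "season_period")
})

test_that("secular trend starts at +50% odds and decays to zero over 10 months", {
  pn <- sim_params(trend = "none")
  expect_equal(trend_log_odds(1:24, pn), rep(0, 24))
  pl <- sim_params(trend = "large")
  expect_equal(trend_log_odds(1, pl), log(1.5))
  expect_equal(trend_log_odds(6, pl), log(1.5) / 2)
  expect_equal(trend_log_odds(11, pl), 0)
  expect_equal(trend_log_odds(20, pl), 0)
})

test_that("cohort generator draws Poisson sector sizes and the stated RE variances", {
  des <- sw_design(wedge_order = 1:12)
  p <- sim_params()
  co <- generate_cohort(des, p, seed = 42)
  expect_true(all(co$group == des$sector_group[as.character(co$sector)]))
  expect_identical(co, generate_cohort(des, p, seed = 42))

  # sector sizes: mean within 3 Poisson SEs of 35 over many sectors
  sizes <- unlist(lapply(1:25, function(s)
    tabulate(generate_cohort(des, p, seed = 100 + s)$sector, 48)))
  expect_equal(mean(sizes), 35, tolerance = 3 * sqrt(35 / length(sizes)) / 35)

  # child random effects have the stated variance at large n
  big <- do.call(rbind, lapply(1:10, function(s)
    generate_cohort(des, p, seed = 200 + s)))
  expect_gt(nrow(big), 10000)
  expect_equal(var(big$u_child), 0.10, tolerance = 0.012)
  # village effects: one value per sector-draw, variance ~0.025 (so village
  # rates spread by roughly +/-30%, i.e. 2*sqrt(0.025) on the log-odds scale)
  u_v <- unlist(lapply(1:15, function(s) {
    co <- generate_cohort(des, p, seed = 400 + s)
    tapply(co$u_sector, co$sector, `[`, 1)
  }))
  expect_equal(var(u_v), 0.025, tolerance = 0.25)
  empty <- generate_cohort(des, sim_params(mean_children_per_sector = 0), seed = 1)
  expect_equal(nrow(empty), 0L)
})

test_that("panel generator is calibrated and encodes the intervention effect", {
  des <- sw_design(wedge_order = randomize_wedge_order(12, seed = 8))
  # degenerate scenario: no REs, no seasonality, theta = 0 -> one shared
  # Bernoulli probability and an annual rate of ~1 episode-positive period
  p0 <- sim_params(theta = 0, var_village = 0, var_child = 0,
                   season_amplitude = 1)
  pan0 <- simulate_panel(des, params = p0, seed = 3)
  expect_equal(attr(pan0, "alpha0"), qlogis(1 / 12), tolerance = 1e-6)
  n_cy <- nrow(pan0) / 12
  expect_gt(n_cy, 2000)  # > 2,000 child-years
  rate <- mean(pan0$y) * 12
  se <- 12 * sqrt(mean(pan0$y) * (1 - mean(pan0$y)) / nrow(pan0))
  expect_lt(abs(rate - 1.0), 3 * se)

  # raw stratified odds recover the simulated effect at large n
  pt <- sim_params(theta = -0.3, var_village = 0, var_child = 0,
                   season_amplitude = 1)
  pans <- do.call(rbind, lapply(1:12, function(s)
    simulate_panel(des, params = pt, seed = 300 + s)))
  odds <- function(v) mean(v) / (1 - mean(v))
  or_hat <- odds(pans$y[pans$x == 1]) / odds(pans$y[pans$x == 0])
  expect_equal(log(or_hat), -0.3, tolerance = 0.12)

  # without any crossover, theta is inert: identical stream to theta = 0
  des_flat <- sw_design(pre_months = 24, wedge_months = 12, post_months = 0,
                        wedge_order = 1:12)
  des_flat$crossover[] <- 99  # never crosses within range
  des_flat$total_periods <- 24L
  pa <- simulate_panel(des_flat, params = sim_params(theta = -0.3), seed = 5)
  pb <- simulate_panel(des_flat, params = sim_params(theta = 0), seed = 5)
  expect_identical(pa$y, pb$y)
})

test_that("birthweight generator matches its marginal moments and ICC", {
  # icc = 0 -> i.i.d. normal
  bw0 <- simulate_birthweights(10, 50, icc = 0, seed = 1)
  expect_equal(mean(bw0$weight), 2700, tolerance = 3 * 437 / sqrt(500) / 2700)

  bw <- simulate_birthweights(400, 30, seed = 2)
  n <- nrow(bw)
  deff <- 1 + 29 * 0.03357  # SE of the grand mean is inflated by clustering
  expect_lt(abs(mean(bw$weight) - 2700), 3 * 437 * sqrt(deff / n))
  expect_lt(abs(sd(bw$weight) - 437), 3 * 437 * sqrt(deff) / sqrt(2 * n))
  icc_hat <- icc_anova(bw$weight, bw$cluster)
  expect_equal(icc_hat, 0.03357, tolerance = 0.5)  # single draw, loose
  expect_error(simulate_birthweights(10, 5, icc = 1.2), "icc")

  # treated clusters are shifted by effect_g (SE ~ 16 g with 100 + 100
  # clusters of 30 at the default ICC)
  bws <- simulate_birthweights(200, 30, effect_g = -100,
                               treated = rep(c(TRUE, FALSE), 100), seed = 3)
  diff_hat <- mean(bws$weight[bws$treated]) - mean(bws$weight[!bws$treated])
  expect_lt(abs(diff_hat - (-100)), 48)
})
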