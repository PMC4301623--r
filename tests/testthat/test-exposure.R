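test_that("trimmed 10-minute means discard tail outliers", {
  # constant trace -> every interval equals the constant
  tm <- trimmed_mean_10min(rep(100, 360))
  expect_equal(tm$value, rep(100, 6))
  expect_true(all(tm$valid))
  # one huge spike among 60 samples is trimmed away (3% of 60 -> 1 per tail)
  x <- rep(10, 60); x[37] <- 10000
  expect_equal(trimmed_mean_10min(x)$value, 10)
  # the trimmed mean stays within the window range
  set.seed(2); y <- rlnorm(60, 3, 1)
  expect_true(trimmed_mean_10min(y)$value >= min(y) &&
              trimmed_mean_10min(y)$value <= max(y))
  # sparse interval flagged invalid
  z <- c(rep(50, 30), rep(NA, 30), rep(60, 60))
  tm2 <- trimmed_mean_10min(z)
  expect_equal(tm2$valid, c(FALSE, TRUE))
  expect_error(trimmed_mean_10min(numeric(0)), "empty")
})

test_that("running median of 5 filters spikes, preserves monotone series, is idempotent", {
  expect_equal(running_median5(c(10, 10, 500, 10, 10)), rep(10, 5))
  mono <- c(1, 3, 4, 7, 9, 12, 15)
  expect_equal(running_median5(mono), mono)
  expect_equal(length(running_median5(rnorm(47))), 47L)
  expect_equal(running_median5(c(5, 2)), c(5, 2))
  # repeated filtering reaches a root within a few passes on every toy 0/1
  # sequence, and already-filtered (root) sequences are left unchanged
  for (L in c(5, 8, 10, 12)) {
    grid <- as.matrix(expand.grid(rep(list(c(0, 1)), L)))
    not_rooted <- 0L
    for (i in seq_len(nrow(grid))) {
      y <- grid[i, ]
      for (pass in 1:20) {
        y2 <- running_median5(y)
        if (identical(y2, y)) break
        y <- y2
      }
      if (!identical(running_median5(y), y)) not_rooted <- not_rooted + 1L
    }
    expect_equal(not_rooted, 0L)
  }
})

test_that("daily baseline is the interpolated 10th percentile", {
  expect_equal(daily_baseline(rep(50, 30)), 50)
  expect_equal(daily_baseline(1:100), 10.9)  # type-7 quantile
  set.seed(5); v <- rlnorm(144, 4, 0.8)
  expect_lte(daily_baseline(v), median(v))
  expect_error(daily_baseline(c(NA_real_, NA_real_)), "no valid")
})

test_that("SIT uses a strict 1.2x threshold and is scale-invariant", {
  expect_length(stove_influenced_time(rep(100, 10), 100), 0L)
  expect_equal(stove_influenced_time(c(100, 119, 121, 500), 100), c(3L, 4L))
  expect_equal(stove_influenced_time(c(0, 0.5, 0), 0), 2L)  # degenerate baseline
  expect_error(stove_influenced_time(1:3, 100, multiplier = -1), "multiplier")
  set.seed(8)
  filt <- rlnorm(144, 4, 0.6)
  b <- daily_baseline(filt)
  for (k in c(0.25, 3, 17)) {
    expect_identical(stove_influenced_time(filt, b),
                     stove_influenced_time(k * filt, k * b))
  }
})

test_that("SIP integrates excess concentration linearly over SIT", {
  expect_equal(integrate_sip(c(130, 220), 100, integer(0)), 0)
  expect_equal(integrate_sip(c(130, 220), 100, 1:2), 150)
  expect_error(integrate_sip(c(130, NA), 100, 1:2), "invalid")
  expect_error(integrate_sip(c(130, 220), 100, 3L), "outside")
})

test_that("the full chain is scale-equivariant and vanishes on constant traces", {
  lg <- simulate_logger_trace(duration_h = 20, n_events = 3, noise_cv = 0.15,
                              baseline_drift = 0.1, seed = 21)
  s1 <- exposure_summary(lg$trace)
  for (k in c(0.5, 7)) {
    tk <- lg$trace; tk$value <- k * tk$value
    sk <- exposure_summary(tk)
    expect_identical(sk$sit_intervals, s1$sit_intervals)
    expect_equal(sk$sip_or_sic, k * s1$sip_or_sic)
    expect_equal(sk$baseline, k * s1$baseline)
  }
  # constant trace: zero SIP at any level
  for (lev in c(1, 50, 4000)) {
    sc <- exposure_summary(rep(lev, 18 * 360))
    expect_equal(sc$sip_or_sic, 0)
    expect_length(sc$sit_intervals, 0L)
  }
  # raising one in-SIT average strictly increases SIP
  tr <- lg$trace
  iv <- s1$sit_intervals[1]
  tr$value[((iv - 1) * 60 + 1):(iv * 60)] <- tr$value[((iv - 1) * 60 + 1):(iv * 60)] + 50
  s2 <- exposure_summary(tr)
  expect_gt(s2$sip_or_sic, s1$sip_or_sic)
})

test_that("calibration corrections apply pointwise before averaging and clip negatives", {
  lg <- simulate_logger_trace(duration_h = 18, n_events = 2, noise_cv = 0.1,
                              seed = 33)
  s_id <- exposure_summary(lg$trace, correction = function(v, rh) v)
  s_no <- exposure_summary(lg$trace)
  expect_equal(s_id$sip_or_sic, s_no$sip_or_sic)
  half <- exposure_summary(lg$trace, correction = function(v, rh) v / 2)
  expect_equal(half$sip_or_sic, s_no$sip_or_sic / 2)
  # pipeline order: correcting raw samples == averaging pre-corrected samples
  tr2 <- lg$trace; tr2$value <- 0.7 * tr2$value + 3
  s_pre <- exposure_summary(tr2)
  s_cor <- exposure_summary(lg$trace, correction = function(v, rh) 0.7 * v + 3)
  expect_equal(s_cor$intervals$value, s_pre$intervals$value)
  expect_warning(humidity_correct(data.frame(value = c(1, 2)),
                                  function(v, rh) v - 5), "clipped")
})

test_that("before/after contrasts recover simulated installation effects", {
  set.seed(77)
  H <- 30
  inst <- sample(7:18, H, replace = TRUE)
  rows <- do.call(rbind, lapply(1:H, function(h) {
    tt <- 1:24
    data.frame(household = h, time = tt, install_time = inst[h],
               sip = 1000 + 60 * rnorm(1) + 40 * rnorm(24) -
                 200 * (tt >= inst[h]))
  }))
  ct <- stove_contrast(rows, value = "sip")
  expect_equal(ct["annual", "estimate"], -200,
               tolerance = 3 * ct["annual", "se_robust"] / 200)
  expect_gt(ct["annual", "se_robust"], 0)
  # identical before/after -> both contrasts zero
  flat <- rows; flat$sip <- 500
  cf <- stove_contrast(flat, value = "sip")
  expect_equal(cf["annual", "estimate"], 0, tolerance = 1e-6)
  expect_equal(cf["immediate", "estimate"], 0, tolerance = 1e-6)
  # no seasonality/trend simulated: annual and immediate contrasts agree
  expect_equal(ct["annual", "estimate"], ct["immediate", "estimate"],
               tolerance = 0.15)
  # a household seen only before installation is excluded with a message
  one <- rows[rows$household != 1 | rows$time < inst[1], ]
  expect_message(stove_contrast(one, value = "sip"), "excluded")
})
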