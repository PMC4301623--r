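test_that("detector reproduces hand-traced episode rules", {
  # all-asymptomatic diary -> nothing
  expect_equal(nrow(detect_episodes(mk_diary(rep(FALSE, 10), rep(FALSE, 10)))), 0L)

  # two days with both symptoms both days -> one episode on days 1-2
  d <- mk_diary(c(TRUE, TRUE, rep(FALSE, 8)), c(TRUE, TRUE, rep(FALSE, 8)))
  ep <- detect_episodes(d)
  expect_equal(nrow(ep), 1L)
  expect_equal(as.integer(ep$end_date - ep$start_date), 1L)
  expect_equal(ep$n_days, 2L)

  # a single symptomatic day never qualifies (span < 2)
  d1 <- mk_diary(c(TRUE, rep(FALSE, 9)), c(TRUE, rep(FALSE, 9)))
  expect_equal(nrow(detect_episodes(d1)), 0L)

  # qualifying runs separated by 6 free days merge; by 7 they split
  f6 <- c(TRUE, TRUE, TRUE, rep(FALSE, 6), TRUE, TRUE)
  b6 <- c(TRUE, FALSE, TRUE, rep(FALSE, 6), TRUE, FALSE)
  ep6 <- detect_episodes(mk_diary(f6, b6))
  expect_equal(nrow(ep6), 1L)
  expect_equal(ep6$n_days, 11L)
  expect_equal(ep6$n_gap_days, 6L)

  f7 <- c(TRUE, TRUE, TRUE, rep(FALSE, 7), TRUE, TRUE)
  b7 <- c(TRUE, FALSE, TRUE, rep(FALSE, 7), TRUE, FALSE)
  ep7 <- detect_episodes(mk_diary(f7, b7))
  expect_equal(nrow(ep7), 2L)

  # a merged candidate without any both-symptom day does not qualify
  fo <- c(TRUE, TRUE, rep(FALSE, 8))
  bo <- rep(FALSE, 10)
  expect_equal(nrow(detect_episodes(mk_diary(fo, bo))), 0L)
  # ... unless the weaker two-day reading is requested
  fw <- c(TRUE, FALSE, rep(FALSE, 8))
  bw <- c(FALSE, TRUE, rep(FALSE, 8))
  expect_equal(nrow(detect_episodes(mk_diary(fw, bw))), 0L)
  expect_equal(nrow(detect_episodes(mk_diary(fw, bw), both_same_day = FALSE)), 1L)
})

test_that("input validation rejects malformed diaries", {
  d <- mk_diary(c(TRUE, TRUE), c(TRUE, TRUE))
  expect_error(detect_episodes(rbind(d, d[1, ])), "duplicated")
  gap <- d; gap$date[2] <- gap$date[2] + 5
  expect_error(detect_episodes(gap), "contiguous")
  expect_error(detect_episodes(d[, 1:2]), "missing column")
})

test_that("missing days break runs unless bridged", {
  f <- c(TRUE, TRUE, NA, TRUE, TRUE, rep(FALSE, 5))
  b <- c(TRUE, FALSE, NA, TRUE, FALSE, rep(FALSE, 5))
  d <- mk_diary(f, b)
  # default: the NA day separates two 2-day candidates, each qualifying
  ep <- detect_episodes(d)
  expect_equal(nrow(ep), 2L)
  # bridging one missing day merges them
  ep2 <- detect_episodes(d, bridge_missing = 1)
  expect_equal(nrow(ep2), 1L)
  expect_equal(ep2$n_days, 5L)
})

test_that("padding a diary with symptom-free days never changes the episodes", {
  set.seed(421)
  for (r in 1:50) {
    n <- sample(3:12, 1)
    f <- runif(n) < 0.4
    b <- runif(n) < 0.4
    base <- oracle_detect(f, b)
    for (pad in c(3, 9)) {
      fp <- c(rep(FALSE, pad), f, rep(FALSE, pad))
      bp <- c(rep(FALSE, pad), b, rep(FALSE, pad))
      got <- core_detect(fp, bp)
      expect_equal(unname(got) - pad, unname(base))
    }
  }
})

test_that("detector agrees with the exhaustive oracle on short diaries", {
  # all two-symptom diaries up to length 6 (4^L combinations per length)
  for (L in 1:6) {
    grid <- as.matrix(expand.grid(rep(list(0:3), L)))
    mismatches <- 0L
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      f <- g == 1L | g == 3L
      b <- g == 2L | g == 3L
      if (!identical(unname(core_detect(f, b)), unname(oracle_detect(f, b))))
        mismatches <- mismatches + 1L
    }
    expect_equal(mismatches, 0L)
  }
})

test_that("severity grading applies the exam thresholds strictly", {
  ep <- data.frame(child_id = "a",
                   start_date = as.Date("2011-02-01"),
                   end_date = as.Date("2011-02-04"),
                   n_days = 4L)
  exam <- function(age, rr, date = "2011-02-02", retr = FALSE, unc = FALSE,
                   crack = FALSE, id = "a")
    data.frame(child_id = id, exam_date = as.Date(date), age_months = age,
               respiratory_rate = rr, chest_retractions = retr,
               unconscious = unc, crackles_any_quadrant = crack)

  # age 8 months, RR 62 -> severe via tachypnea (threshold > 60 under 12 mo)
  r <- classify_severe(ep, exam(8, 62))
  expect_true(r$severe); expect_equal(r$criteria, "tachypnea")
  # age 14 months, RR 50 -> not severe (strict > 50 at >= 12 mo)
  expect_false(classify_severe(ep, exam(14, 50))$severe)
  expect_true(classify_severe(ep, exam(14, 51))$severe)
  expect_false(classify_severe(ep, exam(8, 60))$severe)
  # other danger signs
  expect_equal(classify_severe(ep, exam(20, 30, retr = TRUE))$criteria,
               "retractions")
  expect_true(classify_severe(ep, exam(20, 30, crack = TRUE))$severe)
  # no exam in window -> unexamined, not severe; outside-window exam warns
  expect_warning(r2 <- classify_severe(ep, exam(8, 70, date = "2011-03-01")),
                 "outside")
  expect_false(r2$severe)
  expect_equal(r2$criteria, "unexamined")
})

test_that("episode incidence summary reports both at-risk denominators", {
  sim <- simulate_diaries(6, days = 365, episode_rate = 2, seed = 31)
  ep <- detect_episodes(sim$diary)
  s <- episode_summary(ep, sim$diary)
  expect_equal(sum(s$n_episodes), nrow(ep))
  expect_equal(s$days_observed, rep(365L, 6))
  # excluding episode days from person-time can only raise the rate
  has <- s$n_episodes > 0
  expect_true(all(s$rate_excl[has] >= s$rate_incl[has]))
})
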