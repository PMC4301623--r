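#' Trimmed 10-minute interval means of a logger trace
#'
#' Averages a 10-second logger series into consecutive 10-minute intervals
#' using symmetric trimmed means: within each interval the lowest and highest
#' `trim` fraction of samples (floor of the sample count per tail, at least
#' one sample always retained) are dropped before averaging, protecting the
#' averages from short outlier excursions. Intervals with fewer than
#' `min_valid` of their nominal samples present are flagged invalid.
#'
#' @param x numeric vector of samples, or a logger data frame with a `value`
#'   column (see [read_logger()]).
#' @param trim fraction trimmed from each tail (default 0.03).
#' @param sample_s sampling interval of the trace in seconds (default 10).
#' @param window_s averaging window in seconds (default 600).
#' @param min_valid minimum fraction of valid (non-missing) samples for an
#'   interval to count as valid (default 0.75).
#' @return data frame with columns `interval` (1-based), `value` (trimmed
#'   mean; `NA` if no valid samples), `n_valid`, `valid`.
#' @export
trimmed_mean_10min <- function(x, trim = 0.03, sample_s = 10, window_s = 600,
                               min_valid = 0.75) {
  if (is.data.frame(x)) x <- x$value
  x <- as.numeric(x)
  if (length(x) == 0L) stopf("empty trace")
  trim <- check_number(trim, "trim", min = 0, max = 0.5)
  nominal <- max(1L, round(window_s / sample_s))
  interval <- (seq_along(x) - 1L) %/% nominal + 1L
  sp <- split(x, interval)
  value <- vapply(sp, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    mean(v, trim = trim)
  }, numeric(1))
  n_valid <- vapply(sp, function(v) sum(!is.na(v)), integer(1))
  data.frame(interval = as.integer(names(sp)),
             value = unname(value),
             n_valid = unname(n_valid),
             valid = unname(n_valid >= min_valid * nominal))
}

#' Running median of length 5
#'
#' Centered running median with window 5 for interior points; endpoints use
#' shrinking symmetric windows (length 3 for the second and second-to-last
#' points, length 1 — i.e. unchanged — for the first and last), so the output
#' has the same length as the input. Used to remove isolated short-term
#' excursions (e.g. large-particle contamination spikes) from the 10-minute
#' averages before baseline extraction.
#'
#' @param x numeric vector.
#' @return filtered vector of the same length.
#' @export
running_median5 <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0L) stopf("empty sequence")
  if (n <= 2L) return(x)
  if (n <= 4L) {
    y <- x
    y[2L] <- median(x[1:3])
    y[n - 1L] <- median(x[(n - 2L):n])
    return(y)
  }
  y <- as.numeric(runmed(x, 5L, endrule = "keep"))
  y[2L] <- median(x[1:3])
  y[n - 1L] <- median(x[(n - 2L):n])
  y
}

#' Daily exposure baseline
#'
#' The baseline concentration for a monitoring day: the empirical 10th
#' percentile (linear-interpolation quantile, R type 7) of the day's filtered
#' 10-minute values.
#'
#' @param filtered numeric vector of filtered 10-minute values for one day.
#' @param prob quantile probability (default 0.1).
#' @return baseline concentration.
#' @export
daily_baseline <- function(filtered, prob = 0.1) {
  filtered <- filtered[!is.na(filtered)]
  if (!length(filtered)) stopf("no valid intervals in day")
  unname(quantile(filtered, probs = prob, type = 7))
}

#' Stove-influenced time (SIT)
#'
#' The set of 10-minute intervals whose filtered value strictly exceeds
#' `multiplier` times the daily baseline. With a degenerate zero baseline,
#' every interval with a positive filtered value is stove-influenced.
#'
#' @param filtered filtered 10-minute values.
#' @param baseline daily baseline concentration (>= 0).
#' @param multiplier threshold multiple (default 1.2).
#' @return integer vector of stove-influenced interval indices.
#' @export
stove_influenced_time <- function(filtered, baseline, multiplier = 1.2) {
  baseline <- check_number(baseline, "baseline", min = 0)
  multiplier <- check_number(multiplier, "multiplier", min = 0)
  which(!is.na(filtered) & filtered > multiplier * baseline)
}

#' Integrated excess concentration over stove-influenced time (SIP/SIC)
#'
#' Sums the excess of the 10-minute average values over the daily baseline
#' across the stove-influenced intervals, giving the stove-influenced
#' particulate (SIP, for PM2.5 traces) or stove-influenced CO (SIC) in
#' concentration x 10-minute units. By default the unfiltered 10-minute
#' averages are used (the filtered series only defines which intervals are
#' stove-influenced); pass the filtered series to integrate those instead.
#'
#' @param averages_10min 10-minute average values (unfiltered by default).
#' @param baseline daily baseline.
#' @param sit integer interval indices from [stove_influenced_time()].
#' @return integrated excess in concentration x 10-min units.
#' @export
integrate_sip <- function(averages_10min, baseline, sit) {
  if (length(sit) == 0L) return(0)
  if (any(sit < 1L | sit > length(averages_10min)))
    stopf("SIT indices outside the interval range")
  if (anyNA(averages_10min[sit]))
    stopf("SIT references invalid (missing) intervals")
  sum(averages_10min[sit] - baseline)
}

#' Apply a humidity/calibration correction to a logger trace
#'
#' Applies a pluggable pointwise correction `function(value, relative_humidity)`
#' to the raw trace (e.g. a nephelometer humidity calibration against
#' gravimetric measurements). The default is the identity. Corrected values
#' below zero are clipped to zero with a warning. The correction is applied
#' to the raw 10-second samples, before any averaging.
#'
#' @param trace logger data frame with columns `value` and (optionally)
#'   `relative_humidity`.
#' @param correction `function(value, relative_humidity)` or `NULL`.
#' @return the trace with corrected `value`.
#' @export
humidity_correct <- function(trace, correction = NULL) {
  stopifnot(is.data.frame(trace), "value" %in% names(trace))
  if (is.null(correction)) return(trace)
  rh <- trace$relative_humidity %||% rep(NA_real_, nrow(trace))
  v <- correction(trace$value, rh)
  if (length(v) != nrow(trace))
    stopf("correction must return one value per sample")
  neg <- !is.na(v) & v < 0
  if (any(neg)) {
    warnf("correction produced %d negative value(s); clipped to 0", sum(neg))
    v[neg] <- 0
  }
  trace$value <- v
  trace
}

#' Daily exposure summary: baseline, SIT and SIP/SIC
#'
#' Runs the full processing chain on one logger deployment (nominally >= 18 h
#' including all cooking events of the day): optional calibration correction
#' of the 10-second samples, 3%-trimmed 10-minute means, running-median-5
#' filtering, 10th-percentile baseline, stove-influenced time at the 1.2x
#' threshold, and the integrated excess concentration over SIT.
#'
#' @param trace logger data frame (`timestamp`, `value`, optionally
#'   `relative_humidity`, `temperature`) or a numeric vector of 10-second
#'   samples.
#' @param units concentration units label (`"ug/m3"` for PM2.5, `"ppm"` for CO).
#' @param date optional deployment date label.
#' @param correction optional calibration correction, see [humidity_correct()].
#' @param multiplier SIT threshold multiple (default 1.2).
#' @param trim trimmed-mean tail fraction (default 0.03).
#' @param baseline_prob baseline quantile (default 0.1).
#' @param sip_on `"raw"` (default) to integrate unfiltered 10-minute averages,
#'   `"filtered"` to integrate the filtered series.
#' @param sample_s sampling interval in seconds (default 10).
#' @param min_hours minimum deployment length for a valid daily assessment
#'   (default 18).
#' @return an object of class `"exposure_summary"`: a list with `date`,
#'   `baseline`, `sit_intervals`, `sit_minutes`, `sip_or_sic` (conc x 10 min),
#'   `sip_conc_h` (conc x hours), `sip_24h` (rescaled to a 24-h day),
#'   `n_valid_intervals`, `n_intervals`, `duration_h`, `valid_day`, `units`,
#'   and the intermediate `intervals` table.
#' @export
exposure_summary <- function(trace, units = "ug/m3", date = NULL,
                             correction = NULL, multiplier = 1.2,
                             trim = 0.03, baseline_prob = 0.1,
                             sip_on = c("raw", "filtered"),
                             sample_s = 10, min_hours = 18) {
  sip_on <- match.arg(sip_on)
  if (is.numeric(trace)) trace <- data.frame(value = trace)
  trace <- humidity_correct(trace, correction)
  iv <- trimmed_mean_10min(trace$value, trim = trim, sample_s = sample_s)
  iv$value[!iv$valid] <- NA_real_
  ok <- which(!is.na(iv$value))
  if (!length(ok)) stopf("no valid 10-minute intervals in trace")
  filt <- rep(NA_real_, nrow(iv))
  filt[ok] <- running_median5(iv$value[ok])
  iv$filtered <- filt
  base <- daily_baseline(filt, prob = baseline_prob)
  sit <- stove_influenced_time(filt, base, multiplier = multiplier)
  series <- if (sip_on == "raw") iv$value else iv$filtered
  sip <- integrate_sip(series, base, sit)
  duration_h <- nrow(trace) * sample_s / 3600
  structure(list(
    date = date,
    baseline = base,
    sit_intervals = sit,
    sit_minutes = 10 * length(sit),
    sip_or_sic = sip,
    sip_conc_h = sip / 6,
    sip_24h = sip * 24 / duration_h,
    n_valid_intervals = sum(iv$valid),
    n_intervals = nrow(iv),
    duration_h = duration_h,
    valid_day = duration_h >= min_hours,
    units = units,
    intervals = iv
  ), class = "exposure_summary")
}

#' @export
print.exposure_summary <- function(x, ...) {
  cat(sprintf("Exposure summary%s (%s)\n",
              if (!is.null(x$date)) paste0(" for ", x$date) else "", x$units))
  cat(sprintf("  deployment: %.1f h, %d/%d valid 10-min intervals%s\n",
              x$duration_h, x$n_valid_intervals, x$n_intervals,
              if (x$valid_day) "" else "  [below minimum duration]"))
  cat(sprintf("  baseline: %.2f %s\n", x$baseline, x$units))
  cat(sprintf("  SIT: %d intervals (%d min)\n",
              length(x$sit_intervals), x$sit_minutes))
  cat(sprintf("  SIP/SIC: %.1f %s x 10 min (%.1f %s h; %.1f per 24 h)\n",
              x$sip_or_sic, x$units, x$sip_conc_h, x$units, x$sip_24h))
  invisible(x)
}

#' Before/after stove installation exposure contrasts
#'
#' Estimates the change in a daily exposure summary (e.g. SIP) after stove
#' installation from repeated household measurements, adjusting for season
#' (first-order harmonic pair) and secular trend, with household random
#' intercepts. Two contrasts are computed: the annual contrast (all
#' measurements, capturing the average exposure in the year after
#' installation versus the year before) and the immediate contrast
#' (measurements within `window` months of installation only, less
#' confounded by secular change but more variable). Standard errors are
#' reported both model-based and cluster-robust (household-level sandwich).
#'
#' @param data data frame with one row per household-measurement: columns
#'   `household`, `time` (calendar month, numeric), `install_time` (the
#'   household's installation month) and the outcome named by `value`.
#' @param value name of the outcome column (default `"sip"`).
#' @param window half-width in months for the immediate contrast (default 2).
#' @param season_period months per seasonal cycle (default 12).
#' @param adjust include harmonic season + linear secular adjustment
#'   (default TRUE).
#' @return object of class `"stove_contrast"`: a data frame with rows
#'   `annual` and `immediate` and columns `estimate`, `se_model`, `se_robust`,
#'   `n_obs`, `n_households`; households observed on only one side of
#'   installation are excluded from the paired contrasts and listed in
#'   `attr(, "excluded")`.
#' @export
stove_contrast <- function(data, value = "sip", window = 2,
                           season_period = 12, adjust = TRUE) {
  need <- c("household", "time", "install_time", value)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stopf("data is missing column(s): %s", paste(missing_cols, collapse = ", "))
  d <- data.frame(household = factor(data$household),
                  time = as.numeric(data$time),
                  install_time = as.numeric(data$install_time),
                  after = as.integer(data$time >= data$install_time),
                  y = as.numeric(data[[value]]))
  sides <- tapply(d$after, d$household, function(a) length(unique(a)))
  excluded <- names(sides)[sides < 2]
  if (length(excluded)) {
    message(sprintf("%d household(s) observed on only one side of installation excluded: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
    d <- d[!(as.character(d$household) %in% excluded), , drop = FALSE]
    d$household <- droplevels(d$household)
  }
  if (nrow(d) == 0L || nlevels(d$household) == 0L)
    stopf("no household has measurements both before and after installation")

  one <- function(dd, secular = TRUE) {
    # fit on a standardized outcome for numerical stability, rescale after
    sc <- sd(dd$y)
    if (!is.finite(sc) || sc == 0)
      return(c(estimate = 0, se_model = 0, se_robust = 0,
               n_obs = nrow(dd), n_households = nlevels(droplevels(dd$household))))
    dd$y <- dd$y / sc
    if (adjust && length(unique(dd$time)) > 3) {
      dd$s1 <- sin(2 * pi * dd$time / season_period)
      dd$c1 <- cos(2 * pi * dd$time / season_period)
      dd$time_c <- (dd$time - mean(dd$time)) / season_period
      fml <- if (secular) y ~ after + s1 + c1 + time_c + (1 | household)
             else y ~ after + s1 + c1 + (1 | household)
    } else fml <- y ~ after + (1 | household)
    fit <- lme4::lmer(fml, data = dd, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    rob <- lmm_cluster_sandwich(fit)
    est <- lme4::fixef(fit)["after"]
    c(estimate = sc * unname(est),
      se_model = sc * sqrt(diag(as.matrix(vcov(fit)))["after"]),
      se_robust = sc * sqrt(rob["after", "after"]),
      n_obs = nrow(dd), n_households = nlevels(droplevels(dd$household)))
  }
  annual <- one(d)
  imm_d <- d[abs(d$time - d$install_time) <= window, , drop = FALSE]
  keep_h <- tapply(imm_d$after, imm_d$household, function(a) length(unique(a)) == 2)
  imm_d <- imm_d[keep_h[as.character(imm_d$household)] %in% TRUE, , drop = FALSE]
  imm_d$household <- droplevels(imm_d$household)
  # a short window around installation cannot identify a secular slope on
  # top of the step, so the immediate contrast omits the secular term
  immediate <- if (nrow(imm_d) >= 4 && nlevels(droplevels(imm_d$household)) >= 2)
    one(imm_d, secular = FALSE) else rep(NA_real_, 5)
  out <- as.data.frame(rbind(annual = annual, immediate = immediate))
  names(out) <- c("estimate", "se_model", "se_robust", "n_obs", "n_households")
  attr(out, "excluded") <- excluded
  class(out) <- c("stove_contrast", "data.frame")
  out
}

#' @export
print.stove_contrast <- function(x, ...) {
  cat("Before/after stove installation contrasts\n")
  print.data.frame(round(as.data.frame(x), 4))
  ex <- attr(x, "excluded")
  if (length(ex)) cat(sprintf("Excluded (one-sided) households: %s\n",
                              paste(ex, collapse = ", ")))
  invisible(x)
}

# Cluster (random-intercept group) sandwich covariance for an lmer fit with a
# single random intercept. Bread and meat use the marginal covariance
# V_i = sigma2 I + tau2 J implied by the fitted variance components.
lmm_cluster_sandwich <- function(fit) {
  X <- lme4::getME(fit, "X")
  y <- lme4::getME(fit, "y")
  flist <- lme4::getME(fit, "flist")
  if (length(flist) != 1L) stopf("one random-intercept factor expected")
  g <- flist[[1L]]
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[1L]
  sig2 <- vc$vcov[vc$grp == "Residual"]
  # guard against a degenerate zero residual variance (e.g. constant outcome)
  sig2 <- max(sig2, 1e-10 * max(1, tau2))
  beta <- lme4::fixef(fit)
  r <- y - drop(X %*% beta)
  p <- ncol(X)
  A <- matrix(0, p, p)
  M <- matrix(0, p, p)
  G <- nlevels(g)
  if (G < 2L) stopf("cluster-robust variance undefined with a single cluster")
  for (lev in levels(g)) {
    idx <- which(g == lev)
    Xi <- X[idx, , drop = FALSE]
    ri <- r[idx]
    ni <- length(idx)
    # (sigma2 I + tau2 J)^{-1} x = x/sigma2 - tau2 * sum(x) / (sigma2*(sigma2 + ni*tau2))
    Vinv_X <- Xi / sig2 - tau2 * matrix(colSums(Xi), ni, p, byrow = TRUE) /
      (sig2 * (sig2 + ni * tau2))
    A <- A + crossprod(Xi, Vinv_X)
    gi <- crossprod(Vinv_X, ri)
    M <- M + tcrossprod(gi)
  }
  Ainv <- solve(A)
  V <- Ainv %*% M %*% Ainv * G / (G - 1)
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}
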