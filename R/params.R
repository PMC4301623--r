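#' Simulation parameters for the outcome panel generator
#'
#' Bundles the generative assumptions of the trial simulator: cohort size per
#' sector, the marginal ALRI episode rate, log-odds random-intercept variances
#' for village (sector) and child, multiplicative seasonality, and the secular
#' trend scenario. Defaults are the planning assumptions of the trial this
#' package models.
#'
#' @param theta log-odds intervention effect (negative = protective;
#'   planning range -0.1 to -0.3).
#' @param baseline_rate marginal ALRI episode rate, episodes per child-year,
#'   under the null scenario (default 1.0).
#' @param var_village,var_child random-intercept variances on the log-odds
#'   scale for sector ("village") and child (defaults 0.025 and 0.10; these
#'   imply village rates varying by roughly +/-30% and child rates by
#'   +/-60%, i.e. 2*sqrt(variance) on the log scale).
#' @param season_amplitude relative amplitude of the seasonal sinusoid
#'   (default 1.05: peak rates 1.05x and trough rates 1/1.05x the long-term
#'   average; 1 disables seasonality).
#' @param season_period,season_phase period (months, default 12) and phase
#'   shift (months) of the sinusoid. With the default phase 0 the peak falls
#'   at month 3.
#' @param trend secular-trend scenario: `"none"`, or `"large"` (odds increased
#'   by `trend_start_odds_increase` at time 1, decaying linearly to zero over
#'   `trend_decay_months` months).
#' @param trend_start_odds_increase fractional odds increase at time 1 for the
#'   large-trend scenario (default 0.5, i.e. +50%).
#' @param trend_decay_months months over which the trend decays to zero
#'   (default 10).
#' @param mean_children_per_sector Poisson mean of eligible children per
#'   sector (default 35).
#' @return an object of class `"sim_params"`.
#' @export
sim_params <- function(theta = 0,
                       baseline_rate = 1.0,
                       var_village = 0.025,
                       var_child = 0.10,
                       season_amplitude = 1.05,
                       season_period = 12,
                       season_phase = 0,
                       trend = c("none", "large"),
                       trend_start_odds_increase = 0.5,
                       trend_decay_months = 10,
                       mean_children_per_sector = 35) {
  p <- list(
    theta = check_number(theta, "theta"),
    baseline_rate = check_number(baseline_rate, "baseline_rate", min = 0, strict_min = TRUE),
    var_village = check_number(var_village, "var_village", min = 0),
    var_child = check_number(var_child, "var_child", min = 0),
    season_amplitude = check_number(season_amplitude, "season_amplitude", min = 1),
    season_period = check_number(season_period, "season_period", min = 0, strict_min = TRUE),
    season_phase = check_number(season_phase, "season_phase"),
    trend = match.arg(trend),
    trend_start_odds_increase = check_number(trend_start_odds_increase,
                                             "trend_start_odds_increase", min = 0),
    trend_decay_months = check_number(trend_decay_months, "trend_decay_months",
                                      min = 0, strict_min = TRUE),
    mean_children_per_sector = check_number(mean_children_per_sector,
                                            "mean_children_per_sector", min = 0)
  )
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Panel simulation parameters\n")
  cat(sprintf("  theta (log-odds effect): %g\n", x$theta))
  cat(sprintf("  baseline rate: %g episodes/child-year\n", x$baseline_rate))
  cat(sprintf("  variances: village %g, child %g (log-odds scale)\n",
              x$var_village, x$var_child))
  cat(sprintf("  seasonality: amplitude %g, period %g mo, phase %g mo\n",
              x$season_amplitude, x$season_period, x$season_phase))
  cat(sprintf("  trend: %s", x$trend))
  if (x$trend == "large")
    cat(sprintf(" (+%g%% odds at t=1, decaying over %g mo)",
                100 * x$trend_start_odds_increase, x$trend_decay_months))
  cat(sprintf("\n  children per sector: Poisson(%g)\n", x$mean_children_per_sector))
  invisible(x)
}
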