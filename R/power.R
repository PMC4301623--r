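#' Simulation power for one stepped-wedge scenario
#'
#' Estimates the power to reject `theta = 0` for one cell of the power study:
#' simulates `n_sims` outcome panels from the generative model
#' ([simulate_panel()]) at the given true effect and trend scenario, fits the
#' analysis model ([fit_alri_glmm()]) with `v_fit` spline degrees of freedom,
#' and counts Wald rejections at level `alpha`. Non-converged fits are
#' excluded from the denominator and counted. Replicate random streams are
#' keyed by the scenario label and replicate number (not by evaluation
#' order), so cells of a grid are independent of the order they are run in.
#'
#' @param theta true log-odds stove effect.
#' @param trend `"none"` or `"large"` (see [sim_params()]).
#' @param v_fit spline degrees of freedom used in the analysis model
#'   (0, 2 or 8 in the planning study).
#' @param n_sims simulation replicates (default 100, giving a Monte-Carlo SE
#'   of the power below 5 percentage points).
#' @param design an [sw_design()]; the default is the full trial design
#'   (12 groups x 4 sectors, 24 monthly periods).
#' @param params a [sim_params()]; `theta` and `trend` are overridden by the
#'   scenario arguments.
#' @param seed integer base seed for the cell.
#' @param alpha two-sided test size (default 0.05).
#' @param engine Laplace engine passed to [fit_alri_glmm()].
#' @param cluster_level random-effect/cluster level, see [fit_alri_glmm()].
#' @return object of class `"power_cell"`: list with `rejection_rate` (%),
#'   `mc_se` (%), `mean_theta_hat`, `n_converged`, `n_sims`, and the scenario.
#' @export
run_power_cell <- function(theta = -0.3, trend = c("none", "large"),
                           v_fit = 8, n_sims = 100,
                           design = sw_design(), params = sim_params(),
                           seed = 1, alpha = 0.05,
                           engine = c("glmmTMB", "glmer"),
                           cluster_level = c("sector", "group")) {
  trend <- match.arg(trend)
  engine <- match.arg(engine)
  cluster_level <- match.arg(cluster_level)
  n_sims <- check_count(n_sims, "n_sims")
  params$theta <- check_number(theta, "theta")
  params$trend <- trend
  key <- sprintf("cell|theta=%g|trend=%s|v=%d", theta, trend, v_fit)
  zq <- qnorm(1 - alpha / 2)
  theta_hat <- se <- rep(NA_real_, n_sims)
  conv <- logical(n_sims)
  for (r in seq_len(n_sims)) {
    rs <- derive_seed(seed, paste0(key, "|rep=", r))
    panel <- simulate_panel(design, params = params, seed = rs)
    f <- try(fit_alri_glmm(panel, v = v_fit, cluster_level = cluster_level,
                           engine = engine, alpha = alpha), silent = TRUE)
    if (inherits(f, "try-error")) next
    conv[r] <- f$converged
    theta_hat[r] <- f$theta_hat
    se[r] <- f$se_model
  }
  nc <- sum(conv)
  if (nc == 0L) stopf("no replicate converged")
  rej <- abs(theta_hat[conv] / se[conv]) > zq
  p <- mean(rej)
  structure(list(
    theta = theta, trend = trend, v_fit = v_fit, alpha = alpha,
    n_sims = n_sims, n_converged = nc,
    rejection_rate = 100 * p,
    mc_se = 100 * sqrt(p * (1 - p) / nc),
    mean_theta_hat = mean(theta_hat[conv]),
    design_scale = list(n_groups = design$n_groups,
                        sectors_per_group = design$sectors_per_group,
                        mean_children_per_sector = params$mean_children_per_sector,
                        periods = design$total_periods),
    seed = seed, engine = engine
  ), class = "power_cell")
}

#' @export
print.power_cell <- function(x, ...) {
  cat(sprintf("Power cell: theta = %g, trend = %s, v = %d\n",
              x$theta, x$trend, x$v_fit))
  cat(sprintf("  rejection rate: %.1f%% (MC SE %.1f%%), %d/%d converged\n",
              x$rejection_rate, x$mc_se, x$n_converged, x$n_sims))
  cat(sprintf("  mean theta_hat: %.4f\n", x$mean_theta_hat))
  s <- x$design_scale
  cat(sprintf("  scale: %d groups x %d sectors, Poisson(%g) children, %d periods\n",
              s$n_groups, s$sectors_per_group, s$mean_children_per_sector,
              s$periods))
  invisible(x)
}

#' Power grid over effect size, trend and spline dimension
#'
#' Runs [run_power_cell()] over the cross of `thetas`, `trends` and `vs` and
#' returns the rejection-rate table in the layout of the planning study
#' (rows: trend scenario; columns: theta x analysis v). Cell seed streams are
#' keyed by scenario, so results do not depend on grid order.
#'
#' @param thetas true effects (default `c(-0.1, -0.2, -0.3)`).
#' @param trends trend scenarios (default both).
#' @param vs analysis spline dimensions (default `c(0, 2, 8)`).
#' @inheritParams run_power_cell
#' @return object of class `"power_grid"`: data frame with one row per cell
#'   (`theta`, `trend`, `v`, `power`, `mc_se`, `mean_theta_hat`,
#'   `n_converged`).
#' @export
run_power_grid <- function(thetas = c(-0.1, -0.2, -0.3),
                           trends = c("none", "large"), vs = c(0, 2, 8),
                           n_sims = 100, design = sw_design(),
                           params = sim_params(), seed = 1, alpha = 0.05,
                           engine = c("glmmTMB", "glmer"),
                           cluster_level = c("sector", "group")) {
  if (!length(thetas) || !length(trends) || !length(vs))
    stopf("empty scenario grid")
  engine <- match.arg(engine)
  cluster_level <- match.arg(cluster_level)
  rows <- list()
  for (tr in trends) for (th in thetas) for (v in vs) {
    cell <- run_power_cell(theta = th, trend = tr, v_fit = v, n_sims = n_sims,
                           design = design, params = params, seed = seed,
                           alpha = alpha, engine = engine,
                           cluster_level = cluster_level)
    rows[[length(rows) + 1L]] <- data.frame(
      theta = th, trend = tr, v = v, power = cell$rejection_rate,
      mc_se = cell$mc_se, mean_theta_hat = cell$mean_theta_hat,
      n_converged = cell$n_converged)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_sims") <- n_sims
  attr(out, "design_scale") <- list(n_groups = design$n_groups,
                                    sectors_per_group = design$sectors_per_group,
                                    mean_children = params$mean_children_per_sector)
  class(out) <- c("power_grid", "data.frame")
  out
}

#' @export
print.power_grid <- function(x, ...) {
  cat(sprintf("Power (%% rejections of theta = 0; %d replicates per cell)\n",
              attr(x, "n_sims")))
  thetas <- sort(unique(x$theta), decreasing = TRUE)
  vs <- sort(unique(x$v))
  header <- unlist(lapply(thetas, function(th)
    sprintf("th=%g,v=%g", th, vs)))
  tab <- matrix(NA_real_, nrow = length(unique(x$trend)),
                ncol = length(thetas) * length(vs),
                dimnames = list(unique(x$trend), header))
  for (i in seq_len(nrow(x)))
    tab[x$trend[i], sprintf("th=%g,v=%g", x$theta[i], x$v[i])] <- x$power[i]
  print(round(tab, 1))
  invisible(x)
}

#' Minimum detectable difference for a continuous clustered outcome
#'
#' Closed-form minimum detectable mean difference for a two-arm comparison of
#' a continuous outcome (e.g. birthweight in grams) with cluster sampling:
#' `delta = (z_{1-alpha/2} + z_{power}) * sd * sqrt(2 * DE / n_per_group)`,
#' with design effect `DE = 1 + (cluster_size - 1) * icc`.
#'
#' @param n_per_group births per arm.
#' @param sd outcome standard deviation (e.g. 437 g).
#' @param icc intra-cluster correlation (e.g. 0.03357 for birthweight by
#'   sector).
#' @param cluster_size average births per cluster.
#' @param power target power (default 0.8).
#' @param alpha two-sided type-I error (default 0.05).
#' @return minimum detectable difference, in outcome units.
#' @export
mdd_continuous <- function(n_per_group, sd, icc = 0, cluster_size = 1,
                           power = 0.8, alpha = 0.05) {
  n_per_group <- check_number(n_per_group, "n_per_group", min = 0, strict_min = TRUE)
  sd <- check_number(sd, "sd", min = 0, strict_min = TRUE)
  icc <- check_number(icc, "icc", min = 0, max = 1)
  if (icc >= 1) stopf("icc must be < 1")
  power <- check_number(power, "power", min = 0, max = 1, strict_min = TRUE)
  if (power >= 1) stopf("power must be < 1")
  alpha <- check_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  de <- 1 + (cluster_size - 1) * icc
  (qnorm(1 - alpha / 2) + qnorm(power)) * sd * sqrt(2 * de / n_per_group)
}

#' Power for a two-arm comparison of proportions under a design effect
#'
#' Normal-approximation power for detecting a relative reduction in a
#' proportion (e.g. low birthweight) between two equal arms, deflating the
#' per-arm sample size by a cluster design effect:
#' effective n = `n_per_group / deff`, intervention proportion =
#' `p_control * (1 - relative_reduction)`; both rejection tails are counted.
#'
#' @param p_control control-arm proportion (e.g. 0.29 for LBW).
#' @param relative_reduction relative treatment effect (e.g. 0.2 for a 20%
#'   reduction).
#' @param n_per_group enrolled births per arm.
#' @param deff design effect (e.g. 2.36 for LBW by sector; 1 = no clustering).
#' @param alpha two-sided type-I error (default 0.05).
#' @return power as a fraction.
#' @export
power_proportion <- function(p_control, relative_reduction, n_per_group,
                             deff = 1, alpha = 0.05) {
  p1 <- check_number(p_control, "p_control", min = 0, max = 1, strict_min = TRUE)
  if (p1 >= 1) stopf("p_control must be < 1")
  rr <- check_number(relative_reduction, "relative_reduction", min = 0, max = 1)
  n <- check_number(n_per_group, "n_per_group", min = 0, strict_min = TRUE)
  deff <- check_number(deff, "deff", min = 1)
  alpha <- check_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  p2 <- p1 * (1 - rr)
  neff <- n / deff
  se <- sqrt(p1 * (1 - p1) / neff + p2 * (1 - p2) / neff)
  d <- p1 - p2
  zq <- qnorm(1 - alpha / 2)
  pnorm(d / se - zq) + pnorm(-d / se - zq)
}
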