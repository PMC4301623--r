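#' Seasonal rate multiplier
#'
#' Multiplicative seasonality: `amplitude^sin(2*pi*(t - phase)/period)`, so the
#' peak rate is `amplitude` times and the trough `1/amplitude` times the
#' long-term average, and the geometric mean over a full cycle is 1.
#'
#' @param t time in months (vectorized).
#' @param params a [sim_params()].
#' @return positive multiplier(s).
#' @export
seasonal_multiplier <- function(t, params) {
  stopifnot(inherits(params, "sim_params"))
  params$season_amplitude ^
    sin(2 * pi * (t - params$season_phase) / params$season_period)
}

#' Secular-trend log-odds term
#'
#' Under the `"large"` scenario the odds of ALRI are increased by
#' `trend_start_odds_increase` (default +50%) at time 1 and the increase
#' decays linearly to zero over `trend_decay_months` months:
#' `log(1 + inc) * max(0, 1 - (t - 1)/decay)`. Under `"none"` the term is 0.
#'
#' @param t time in months (vectorized).
#' @param params a [sim_params()].
#' @return additive log-odds term(s).
#' @export
trend_log_odds <- function(t, params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$trend == "none") return(rep(0, length(t)))
  log1p(params$trend_start_odds_increase) *
    pmax(0, 1 - (t - 1) / params$trend_decay_months)
}

# Per-period response probability target under the null scenario.
null_period_prob <- function(params, design) {
  ppy <- 12 * design$periods_per_month
  p0 <- params$baseline_rate / ppy
  if (p0 >= 1) stopf("baseline_rate %g exceeds one episode per period", params$baseline_rate)
  p0
}

#' Calibrate the model intercept to the target episode rate
#'
#' Solves for the intercept `alpha0` such that, under the null scenario
#' (no intervention, no secular trend, seasonality as configured), the
#' marginal per-period response probability — averaging over the village and
#' child random intercepts by Gauss-Hermite quadrature and over one seasonal
#' cycle — equals `baseline_rate` divided by the number of periods per year.
#'
#' @param params a [sim_params()].
#' @param design an [sw_design()].
#' @param nq quadrature nodes.
#' @return the calibrated intercept (log-odds scale).
#' @export
calibrate_alpha0 <- function(params, design = sw_design(), nq = 25) {
  stopifnot(inherits(params, "sim_params"), inherits(design, "sw_design"))
  p0 <- null_period_prob(params, design)
  sig <- sqrt(params$var_village + params$var_child)
  gh <- gauss_hermite(nq)
  u <- sqrt(2) * sig * gh$nodes
  w <- gh$weights / sqrt(pi)
  # months covered by one seasonal cycle at the design's granularity
  tm <- seq_len(round(params$season_period * design$periods_per_month)) /
    design$periods_per_month
  soff <- log(seasonal_multiplier(tm, params))
  marg <- function(a0) mean(colSums(w * plogis(outer(u, a0 + soff, `+`)))) - p0
  uniroot(marg, c(-15, 5), tol = 1e-10)$root
}

#' Generate a simulated trial cohort
#'
#' Draws the number of eligible children in each sector from a Poisson
#' distribution (mean `mean_children_per_sector`) and attaches each sector's
#' village random intercept and each child's own random intercept, drawn from
#' mean-zero normals with variances `var_village` and `var_child`.
#'
#' @param design an [sw_design()].
#' @param params a [sim_params()].
#' @param seed integer seed for reproducibility.
#' @return data frame with one row per child: `child_id`, `sector`, `group`,
#'   `u_sector`, `u_child`.
#' @export
generate_cohort <- function(design = sw_design(), params = sim_params(),
                            seed = NULL) {
  stopifnot(inherits(design, "sw_design"), inherits(params, "sim_params"))
  with_seed(seed, {
    n_sectors <- length(design$sector_group)
    n_ch <- rpois(n_sectors, params$mean_children_per_sector)
    u_sector <- rnorm(n_sectors, 0, sqrt(params$var_village))
    n <- sum(n_ch)
    sector <- rep(seq_len(n_sectors), n_ch)
    out <- data.frame(
      child_id = if (n) sprintf("c%05d", seq_len(n)) else character(0),
      sector = sector,
      group = unname(design$sector_group[as.character(sector)]),
      u_sector = u_sector[sector],
      u_child = rnorm(n, 0, sqrt(params$var_child))
    )
    attr(out, "design") <- design
    out
  })
}

#' Simulate a stepped-wedge outcome panel
#'
#' Generates one binary ALRI response per child-period from the logistic
#' random-intercept model: `logit p = alpha0 + u_sector + u_child +
#' log(seasonal multiplier) + trend + theta * x`, where `x` is the
#' stepped-wedge exposure indicator implied by the design and `alpha0` is
#' calibrated by [calibrate_alpha0()] so the null-scenario marginal episode
#' rate equals `baseline_rate`.
#'
#' @param design an [sw_design()].
#' @param cohort a cohort from [generate_cohort()] (generated against the
#'   same design); generated on the fly if omitted.
#' @param params a [sim_params()].
#' @param seed integer seed.
#' @return data frame with columns `child_id`, `sector`, `group`, `period`,
#'   `x`, `y`, with the calibrated intercept in `attr(, "alpha0")`.
#' @export
simulate_panel <- function(design = sw_design(), cohort = NULL,
                           params = sim_params(), seed = NULL) {
  stopifnot(inherits(design, "sw_design"), inherits(params, "sim_params"))
  with_seed(seed, {
    if (is.null(cohort)) cohort <- generate_cohort(design, params)
    cd <- attr(cohort, "design")
    if (!is.null(cd) && !identical(cd$sector_group, design$sector_group))
      stopf("cohort was generated against a different design")
    alpha0 <- calibrate_alpha0(params, design)
    n <- nrow(cohort)
    Tt <- design$total_periods
    period <- rep(seq_len(Tt), times = n)
    idx <- rep(seq_len(n), each = Tt)
    tm <- period / design$periods_per_month   # months
    x <- intervention_indicator(design, cohort$group[idx], period)
    eta <- alpha0 + cohort$u_sector[idx] + cohort$u_child[idx] +
      log(seasonal_multiplier(tm, params)) + trend_log_odds(tm, params) +
      params$theta * ifelse(is.na(x), 0L, x)
    y <- rbinom(length(eta), 1L, plogis(eta))
    out <- data.frame(
      child_id = cohort$child_id[idx],
      sector = cohort$sector[idx],
      group = cohort$group[idx],
      period = period, x = x, y = y
    )
    attr(out, "alpha0") <- alpha0
    attr(out, "design") <- design
    attr(out, "params") <- params
    out
  })
}

#' Simulate clustered birthweights
#'
#' Generates birthweights with an exchangeable within-cluster correlation:
#' cluster effects are Normal(0, `icc * sd_g^2`) and child deviations
#' Normal(0, `(1 - icc) * sd_g^2`), so the marginal mean and SD are `mean_g`
#' and `sd_g` and the intra-cluster correlation is `icc`. Clusters flagged in
#' `treated` are shifted by `effect_g` grams.
#'
#' @param n_clusters number of clusters (sectors).
#' @param cluster_sizes integer vector of births per cluster, recycled to
#'   `n_clusters`.
#' @param mean_g,sd_g marginal mean and SD in grams (defaults 2700, 437).
#' @param icc intra-cluster correlation in `[0, 1)` (default 0.03357).
#' @param effect_g additive treatment effect in grams for treated clusters.
#' @param treated logical vector per cluster (default all untreated).
#' @param seed integer seed.
#' @return data frame `cluster`, `treated`, `weight`.
#' @export
simulate_birthweights <- function(n_clusters, cluster_sizes,
                                  mean_g = 2700, sd_g = 437, icc = 0.03357,
                                  effect_g = 0, treated = NULL, seed = NULL) {
  n_clusters <- check_count(n_clusters, "n_clusters")
  sd_g <- check_number(sd_g, "sd_g", min = 0, strict_min = TRUE)
  icc <- check_number(icc, "icc", min = 0, max = 1)
  if (icc >= 1) stopf("icc must be < 1")
  sizes <- rep_len(as.integer(cluster_sizes), n_clusters)
  treated <- rep_len(treated %||% FALSE, n_clusters)
  with_seed(seed, {
    a <- rnorm(n_clusters, 0, sqrt(icc) * sd_g)
    cl <- rep(seq_len(n_clusters), sizes)
    w <- mean_g + a[cl] + rnorm(sum(sizes), 0, sqrt(1 - icc) * sd_g) +
      effect_g * treated[cl]
    data.frame(cluster = cl, treated = treated[cl], weight = w)
  })
}

#' One-way ANOVA estimator of the intra-cluster correlation
#'
#' Method-of-moments ICC from the one-way ANOVA decomposition, using the
#' standard unbalanced-design average cluster size
#' `n0 = (N - sum(n_i^2)/N) / (k - 1)`.
#'
#' @param y numeric outcome.
#' @param cluster cluster labels.
#' @return estimated ICC (can be slightly negative by sampling error).
#' @export
icc_anova <- function(y, cluster) {
  cluster <- factor(cluster)
  k <- nlevels(cluster)
  if (k < 2) stopf("need at least 2 clusters")
  N <- length(y)
  ni <- tabulate(cluster)
  means <- tapply(y, cluster, mean)
  grand <- mean(y)
  ssb <- sum(ni * (means - grand)^2)
  ssw <- sum((y - means[cluster])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  (msb - msw) / (msb + (n0 - 1) * msw)
}
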