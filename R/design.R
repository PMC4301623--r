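#' Stepped-wedge trial design
#'
#' Container for the structure of a cluster-randomized, modified stepped-wedge
#' trial: `n_groups` randomization groups of `sectors_per_group` sectors each,
#' observed for a pre-rollout phase, a rollout ("wedge") phase in which one
#' group crosses over to the intervention per wedge month, and a post-rollout
#' phase. The default reproduces the trial this package models: 12 groups of
#' 4 sectors, 6 + 12 + 6 months, 24 monthly periods in total.
#'
#' Sectors are assigned to groups by round-robin striping across the supplied
#' geographic ordering (`sector_order`), mimicking a stratified systematic
#' spread of each group's sectors across the study area.
#'
#' @param n_groups number of randomization groups; must equal `wedge_months`
#'   so that crossover months form a bijection from groups onto wedge months.
#' @param sectors_per_group sectors in each group.
#' @param pre_months,wedge_months,post_months phase lengths in months.
#' @param wedge_order integer permutation of `1:n_groups`; `wedge_order[k]` is
#'   the group whose stoves are installed in wedge month `k`. Defaults to the
#'   identity ordering; use [randomize_wedge_order()] for a random draw.
#' @param transition coding of the installation month itself:
#'   `"unexposed"` (default; installation takes place over the month, so the
#'   month is not counted as exposed time), `"exposed"`, or `"drop"` (the
#'   month is excluded from analysis; [intervention_indicator()] returns `NA`).
#' @param period_unit `"month"` (default) or `"week"`. Weekly granularity
#'   maps each month boundary to `round(month * 52/12)` weeks.
#' @param sector_order optional permutation of `1:(n_groups*sectors_per_group)`
#'   giving the geographic ordering used for round-robin group assignment.
#'
#' @return an object of class `"sw_design"` with elements including
#'   `crossover` (named vector: group -> calendar installation period) and
#'   `sector_group` (named vector: sector -> group).
#' @seealso [randomize_wedge_order()], [intervention_indicator()]
#' @export
#' @examples
#' d <- sw_design(wedge_order = randomize_wedge_order(12, seed = 1))
#' d
sw_design <- function(n_groups = 12, sectors_per_group = 4,
                      pre_months = 6, wedge_months = 12, post_months = 6,
                      wedge_order = NULL,
                      transition = c("unexposed", "exposed", "drop"),
                      period_unit = c("month", "week"),
                      sector_order = NULL) {
  n_groups <- check_count(n_groups, "n_groups")
  sectors_per_group <- check_count(sectors_per_group, "sectors_per_group")
  pre_months <- check_count(pre_months, "pre_months", min = 0L)
  wedge_months <- check_count(wedge_months, "wedge_months")
  post_months <- check_count(post_months, "post_months", min = 0L)
  transition <- match.arg(transition)
  period_unit <- match.arg(period_unit)
  if (n_groups != wedge_months)
    stopf("n_groups (%d) must equal wedge_months (%d): one group crosses over per wedge month",
          n_groups, wedge_months)
  wedge_order <- wedge_order %||% seq_len(n_groups)
  if (!setequal(wedge_order, seq_len(n_groups)) || length(wedge_order) != n_groups)
    stopf("wedge_order must be a permutation of 1:%d", n_groups)

  n_sectors <- n_groups * sectors_per_group
  sector_order <- sector_order %||% seq_len(n_sectors)
  if (!setequal(sector_order, seq_len(n_sectors)))
    stopf("sector_order must be a permutation of 1:%d", n_sectors)
  # round-robin striping: walk the geographic ordering, dealing sectors to
  # groups 1..n_groups cyclically
  sector_group <- integer(n_sectors)
  sector_group[sector_order] <- rep_len(seq_len(n_groups), n_sectors)
  names(sector_group) <- as.character(seq_len(n_sectors))

  ppm <- if (period_unit == "month") 1 else 52 / 12
  months_total <- pre_months + wedge_months + post_months
  total_periods <- round(months_total * ppm)
  # calendar installation period of each group (group g installed in wedge
  # month position match(g, wedge_order))
  position <- match(seq_len(n_groups), wedge_order)
  crossover <- round((pre_months + position) * ppm)
  names(crossover) <- as.character(seq_len(n_groups))

  structure(list(
    n_groups = n_groups, sectors_per_group = sectors_per_group,
    pre_months = pre_months, wedge_months = wedge_months,
    post_months = post_months, wedge_order = as.integer(wedge_order),
    transition = transition, period_unit = period_unit,
    periods_per_month = ppm, total_periods = as.integer(total_periods),
    crossover = crossover, sector_group = sector_group
  ), class = "sw_design")
}

#' @export
print.sw_design <- function(x, ...) {
  cat(sprintf("Stepped-wedge design: %d groups x %d sectors (%d sectors)\n",
              x$n_groups, x$sectors_per_group, length(x$sector_group)))
  cat(sprintf("Phases (months): pre %d | wedge %d | post %d; %d %s periods\n",
              x$pre_months, x$wedge_months, x$post_months,
              x$total_periods, x$period_unit))
  cat(sprintf("Installation month coded: %s\n", x$transition))
  cat("Crossover periods by group:\n")
  print(x$crossover)
  invisible(x)
}

#' Randomize the wedge order
#'
#' Draws a uniformly random permutation of the groups, emulating the field
#' procedure of drawing numbered slips from a hat: the group drawn first has
#' its stoves installed in the first wedge month, and so on.
#'
#' @param n_groups number of groups (>= 1).
#' @param seed integer seed; the draw is reproducible for a fixed seed.
#' @return integer vector; element `k` is the group installed in wedge month `k`.
#' @export
randomize_wedge_order <- function(n_groups, seed = NULL) {
  n_groups <- check_count(n_groups, "n_groups")
  with_seed(seed, sample.int(n_groups))
}

#' Intervention (exposure) indicator for a group-period
#'
#' Returns the stepped-wedge exposure covariate: 0 before a group's stove
#' installation, 1 strictly after it. The installation period itself is coded
#' according to the design's `transition` rule (default unexposed; `"drop"`
#' yields `NA`).
#'
#' @param design an [sw_design()].
#' @param group group identifier(s).
#' @param period period index/indices in `1:design$total_periods`.
#' @return integer 0/1 vector (possibly `NA` under `transition = "drop"`),
#'   recycled over `group` and `period`.
#' @export
intervention_indicator <- function(design, group, period) {
  stopifnot(inherits(design, "sw_design"))
  group <- as.character(group)
  bad <- setdiff(unique(group), names(design$crossover))
  if (length(bad)) stopf("unknown group(s): %s", paste(bad, collapse = ", "))
  if (any(period < 1 | period > design$total_periods))
    stopf("period must be within 1..%d", design$total_periods)
  co <- unname(design$crossover[group])
  x <- as.integer(period > co)
  at <- which(period == co)
  if (length(at)) {
    x[at] <- switch(design$transition,
                    unexposed = 0L, exposed = 1L, drop = NA_integer_)
  }
  x
}

#' Stratified individual randomization (phase-two style)
#'
#' Randomizes households to two arms with balanced permuted assignment within
#' each stratum, separately for prior trial participants and newly eligible
#' households. Within every stratum x prior-participation cell the two arm
#' counts differ by at most one. The assignment is a deterministic function of
#' `seed` and the household identifiers: the random stream for each cell is
#' keyed by the cell label, so shuffling the input rows does not change any
#' household's arm.
#'
#' @param households data frame with columns `household_id`, `stratum` (or the
#'   pair `vdc` and `ward`, combined into a stratum), and logical
#'   `prior_participant`.
#' @param seed integer seed.
#' @param arms length-2 character vector of arm labels.
#' @return data frame `household_id`, `stratum`, `prior_participant`, `arm`.
#' @export
randomize_phase2 <- function(households, seed = NULL,
                             arms = c("biomass_chimney", "LPG")) {
  if (!is.data.frame(households) || nrow(households) == 0L)
    stopf("`households` must be a non-empty data frame")
  if (length(arms) != 2L) stopf("exactly two arms are required")
  h <- as.data.frame(households)
  if (!"stratum" %in% names(h)) {
    if (!all(c("vdc", "ward") %in% names(h)))
      stopf("`households` needs a `stratum` column or both `vdc` and `ward`")
    h$stratum <- paste(h$vdc, h$ward, sep = ":")
  }
  if (anyNA(h$stratum)) stopf("every household must have a stratum")
  if (!"prior_participant" %in% names(h)) h$prior_participant <- FALSE
  if (anyDuplicated(h$household_id))
    stopf("duplicated household_id values")

  h$arm <- NA_character_
  cells <- split(seq_len(nrow(h)),
                 list(stratum = h$stratum, prior = h$prior_participant),
                 drop = TRUE)
  for (key in sort(names(cells))) {
    idx <- cells[[key]]
    idx <- idx[order(as.character(h$household_id[idx]))]
    n <- length(idx)
    base <- rep(arms, n %/% 2L)
    cell_seed <- if (is.null(seed)) NULL else derive_seed(seed, key)
    assignment <- with_seed(cell_seed, {
      extra <- if (n %% 2L) sample(arms, 1L) else character(0)
      sample(c(base, extra))
    })
    h$arm[idx] <- assignment
  }
  out <- h[, c("household_id", "stratum", "prior_participant", "arm")]
  rownames(out) <- NULL
  out
}
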