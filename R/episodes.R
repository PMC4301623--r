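#' ALRI episode detection from daily symptom diaries
#'
#' Classifies a child's daily symptom diary into episodes of acute lower
#' respiratory infection (ALRI). The rule: an episode is a maximal set of
#' symptomatic days (days with fever and/or fast/difficult breathing) in which
#' consecutive symptomatic days are separated by at most `max_gap` (default 6)
#' symptom-free days, spanning at least two calendar days from first to last
#' symptomatic day, and containing at least one day on which fever and
#' fast/difficult breathing are both reported. Distinct episodes are therefore
#' separated by at least `max_gap + 1` (default 7) symptom-free days.
#' Symptom-free days inside an episode (gap days) are retained in the episode
#' span and counted in `n_gap_days`.
#'
#' Days with missing symptom reports (`NA`) break runs by default: no episode
#' may span a missing day. Setting `bridge_missing = k` treats runs of up to
#' `k` consecutive missing days as symptom-free days instead.
#'
#' With `both_same_day = FALSE` the qualification is weakened to "fever on
#' some day and fast/difficult breathing on some (possibly different) day of
#' the episode".
#'
#' @param diary data frame with columns `child_id`, `date` (Date or ISO-8601
#'   string), and logical/0-1 columns `fever` and `fast_difficult_breathing`
#'   (further symptom columns are allowed and ignored here). One row per
#'   child-day; dates must be contiguous within each child (insert rows with
#'   `NA` symptoms for missing days).
#' @param max_gap largest number of symptom-free days merged into an episode
#'   (default 6, i.e. episodes are separated by >= 7 symptom-free days).
#' @param both_same_day require fever and fast/difficult breathing on a single
#'   day (default) rather than on possibly different days.
#' @param bridge_missing bridge runs of up to this many consecutive missing
#'   days (default 0 = missing days break runs).
#' @return data frame with one row per episode: `child_id`, `start_date`,
#'   `end_date`, `n_days` (calendar span), `n_symptom_days`, `n_gap_days`.
#' @export
#' @examples
#' d <- data.frame(child_id = "a",
#'                 date = as.Date("2011-01-01") + 0:9,
#'                 fever = c(1,1,0,0,0,0,0,0,0,0),
#'                 fast_difficult_breathing = c(1,1,0,0,0,0,0,0,0,0))
#' detect_episodes(d)
detect_episodes <- function(diary, max_gap = 6, both_same_day = TRUE,
                            bridge_missing = 0) {
  diary <- validate_diary(diary)
  max_gap <- check_count(max_gap, "max_gap", min = 0L)
  bridge_missing <- check_count(bridge_missing, "bridge_missing", min = 0L)
  res <- lapply(split(diary, diary$child_id, drop = TRUE), function(d) {
    d <- d[order(d$date), , drop = FALSE]
    f <- as.logical(d$fever)
    b <- as.logical(d$fast_difficult_breathing)
    miss <- is.na(f) | is.na(b)
    ep <- detect_core(f, b, miss, max_gap = max_gap,
                      both_same_day = both_same_day,
                      bridge_missing = bridge_missing)
    if (nrow(ep) == 0L) return(NULL)
    data.frame(child_id = d$child_id[1],
               start_date = d$date[ep[, "start"]],
               end_date = d$date[ep[, "end"]],
               n_days = ep[, "end"] - ep[, "start"] + 1L,
               n_symptom_days = ep[, "n_sympt"],
               n_gap_days = ep[, "n_gap"])
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(child_id = character(0),
                      start_date = as.Date(character(0)),
                      end_date = as.Date(character(0)),
                      n_days = integer(0), n_symptom_days = integer(0),
                      n_gap_days = integer(0))
  rownames(out) <- NULL
  out
}

validate_diary <- function(diary) {
  if (!is.data.frame(diary))
    stopf("`diary` must be a data frame")
  need <- c("child_id", "date", "fever", "fast_difficult_breathing")
  missing_cols <- setdiff(need, names(diary))
  if (length(missing_cols))
    stopf("diary is missing column(s): %s", paste(missing_cols, collapse = ", "))
  diary$date <- as.Date(diary$date)
  for (id in unique(diary$child_id)) {
    dd <- sort(diary$date[diary$child_id == id])
    if (anyDuplicated(dd))
      stopf("duplicated diary days for child %s", id)
    if (length(dd) > 1L && any(diff(as.integer(dd)) != 1L))
      stopf("diary days for child %s are not contiguous; insert NA rows for missing days", id)
  }
  diary
}

# Core detector on logical vectors for one child.
# f, b: fever / fast-difficult-breathing; miss: missing-day flag.
# Returns matrix with columns start, end, n_sympt, n_gap.
detect_core <- function(f, b, miss = rep(FALSE, length(f)), max_gap = 6,
                        both_same_day = TRUE, bridge_missing = 0) {
  empty <- matrix(integer(0), 0, 4,
                  dimnames = list(NULL, c("start", "end", "n_sympt", "n_gap")))
  n <- length(f)
  if (n == 0L) return(empty)
  f[miss] <- FALSE; b[miss] <- FALSE
  sym <- f | b
  # hard breaks at unbridged missing-day runs
  if (any(miss)) {
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hard <- r$values & r$lengths > bridge_missing
    miss_block <- logical(n)
    for (i in which(hard)) miss_block[starts[i]:ends[i]] <- TRUE
  } else miss_block <- logical(n)

  d <- which(sym)
  if (length(d) == 0L) return(empty)
  # split symptomatic days into episodes: a new episode starts when the gap
  # to the previous symptomatic day exceeds max_gap free days, or a hard
  # missing-day block intervenes
  if (length(d) > 1L) {
    gap_free <- diff(d) - 1L
    new_ep <- gap_free > max_gap
    if (any(miss_block)) {
      cmb <- cumsum(miss_block)
      blocked <- cmb[d[-1L]] - cmb[d[-length(d)]] > 0L
      new_ep <- new_ep | blocked
    }
    brk <- which(new_ep)
    starts <- d[c(1L, brk + 1L)]
    ends <- d[c(brk, length(d))]
  } else {
    starts <- d
    ends <- d
  }
  keep <- logical(length(starts))
  nsym <- integer(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    span <- e - s + 1L
    nsym[i] <- sum(sym[s:e])
    qual <- if (both_same_day) any(f[s:e] & b[s:e])
            else any(f[s:e]) && any(b[s:e])
    keep[i] <- span >= 2L && qual
  }
  if (!any(keep)) return(empty)
  s <- as.integer(starts[keep]); e <- as.integer(ends[keep])
  cbind(start = s, end = e, n_sympt = nsym[keep],
        n_gap = (e - s + 1L) - nsym[keep])
}

#' Grade episode severity from case examinations
#'
#' An ALRI episode is graded severe if any case examination dated within the
#' episode window shows at least one of: tachypnea (respiratory rate > 50
#' breaths/min for children 12 months or older, > 60 for children under 12
#' months; strict inequalities), chest retractions, unconsciousness, or
#' crackles in at least one quadrant on auscultation. Episodes with no
#' examination in their window are graded not severe and flagged
#' `"unexamined"`. Examinations falling outside every episode window are
#' ignored with a warning.
#'
#' @param episodes episode table from [detect_episodes()].
#' @param exams data frame with columns `child_id`, `exam_date`, `age_months`,
#'   `respiratory_rate`, `chest_retractions`, `unconscious`,
#'   `crackles_any_quadrant` (and optionally `oxygen_saturation`).
#' @return `episodes` with added columns `severe` (logical), `criteria`
#'   (comma-separated subset of tachypnea/retractions/unconsciousness/crackles,
#'   or `"unexamined"`), `n_exams`.
#' @export
classify_severe <- function(episodes, exams) {
  stopifnot(is.data.frame(episodes))
  if (!is.data.frame(exams))
    stopf("`exams` must be a data frame")
  need <- c("child_id", "exam_date", "age_months", "respiratory_rate",
            "chest_retractions", "unconscious", "crackles_any_quadrant")
  missing_cols <- setdiff(need, names(exams))
  if (length(missing_cols))
    stopf("exams is missing column(s): %s", paste(missing_cols, collapse = ", "))
  exams$exam_date <- as.Date(exams$exam_date)
  if (any(exams$respiratory_rate <= 0, na.rm = TRUE))
    stopf("respiratory_rate must be positive")

  episodes$severe <- FALSE
  episodes$criteria <- ""
  episodes$n_exams <- 0L
  used <- logical(nrow(exams))
  for (i in seq_len(nrow(episodes))) {
    sel <- exams$child_id == episodes$child_id[i] &
      exams$exam_date >= episodes$start_date[i] &
      exams$exam_date <= episodes$end_date[i]
    used <- used | sel
    ex <- exams[sel, , drop = FALSE]
    episodes$n_exams[i] <- nrow(ex)
    if (nrow(ex) == 0L) {
      episodes$criteria[i] <- "unexamined"
      next
    }
    tachy <- (ex$age_months >= 12 & ex$respiratory_rate > 50) |
             (ex$age_months < 12 & ex$respiratory_rate > 60)
    crit <- c(
      tachypnea = any(tachy, na.rm = TRUE),
      retractions = any(as.logical(ex$chest_retractions), na.rm = TRUE),
      unconsciousness = any(as.logical(ex$unconscious), na.rm = TRUE),
      crackles = any(as.logical(ex$crackles_any_quadrant), na.rm = TRUE)
    )
    episodes$severe[i] <- any(crit)
    episodes$criteria[i] <- paste(names(crit)[crit], collapse = ",")
  }
  if (any(!used))
    warnf("%d examination(s) fell outside every episode window and were ignored",
          sum(!used))
  episodes
}

#' Child-level episode incidence summary
#'
#' Computes episodes per child-year at risk. Because the at-risk denominator
#' is not uniquely defined, both conventions are reported: person-time
#' including episode days, and person-time excluding days spent in an episode.
#'
#' @param episodes episode table from [detect_episodes()].
#' @param diary the diary the episodes were detected from (defines follow-up
#'   days; days with missing symptom reports are not counted as observed).
#' @return data frame per child: `child_id`, `n_episodes`, `days_observed`,
#'   `days_in_episode`, `rate_incl` and `rate_excl` (episodes per child-year
#'   with the two denominators).
#' @export
episode_summary <- function(episodes, diary) {
  diary <- validate_diary(diary)
  obs <- !(is.na(diary$fever) | is.na(diary$fast_difficult_breathing))
  days_obs <- tapply(obs, diary$child_id, sum)
  ids <- names(days_obs)
  n_ep <- table(factor(episodes$child_id, levels = ids))
  d_ep <- tapply(episodes$n_days, factor(episodes$child_id, levels = ids), sum)
  d_ep[is.na(d_ep)] <- 0
  out <- data.frame(
    child_id = ids,
    n_episodes = as.integer(n_ep),
    days_observed = as.integer(days_obs),
    days_in_episode = as.integer(d_ep)
  )
  out$rate_incl <- out$n_episodes / (out$days_observed / 365.25)
  at_risk <- pmax(out$days_observed - out$days_in_episode, 0L)
  out$rate_excl <- ifelse(at_risk > 0, out$n_episodes / (at_risk / 365.25), NA_real_)
  rownames(out) <- NULL
  out
}
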