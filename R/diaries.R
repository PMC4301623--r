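#' Simulate daily symptom diaries with planted ALRI episodes
#'
#' Generates per-child daily diaries of the six maternally reported symptoms,
#' with ALRI episodes planted so that they satisfy the episode definition used
#' by [detect_episodes()]: each planted episode spans 2 or more days, every
#' episode day carries fever and/or fast/difficult breathing, at least one day
#' carries both, and planted episodes are separated by at least 7 symptom-free
#' days. Optional non-qualifying noise days (isolated single-symptom days,
#' placed at least 8 days from any planted episode so they can neither extend
#' nor merge with one) emulate everyday symptom reporting. The planted
#' episodes are returned as ground truth for round-trip testing of the
#' detector.
#'
#' @param n_children number of children.
#' @param days follow-up days per child (default 365).
#' @param episode_rate planted episodes per child-year (default 1.0).
#' @param noise_rate expected isolated noise symptom-days per child-year
#'   (default 0).
#' @param length_range inclusive range of episode lengths in days
#'   (default `c(2, 7)`).
#' @param start_date first diary date (default `"2011-01-01"`).
#' @param seed integer seed.
#' @return list with elements `diary` (data frame: `child_id`, `date`, and
#'   logical `fever`, `fast_difficult_breathing`, `persistent_cough`,
#'   `wheezing`, `watery_stool`, `ear_discharge`) and `episodes` (ground
#'   truth: `child_id`, `start_date`, `end_date`, `n_days`).
#' @export
simulate_diaries <- function(n_children, days = 365, episode_rate = 1.0,
                             noise_rate = 0, length_range = c(2, 7),
                             start_date = "2011-01-01", seed = NULL) {
  n_children <- check_count(n_children, "n_children")
  days <- check_count(days, "days", min = 1L)
  episode_rate <- check_number(episode_rate, "episode_rate", min = 0, strict_min = TRUE)
  noise_rate <- check_number(noise_rate, "noise_rate", min = 0)
  if (length_range[1] < 2) stopf("episodes must span at least 2 days")
  start_date <- as.Date(start_date)
  sep <- 7L  # required symptom-free days between episodes

  with_seed(seed, {
    diaries <- vector("list", n_children)
    truths <- vector("list", n_children)
    for (ci in seq_len(n_children)) {
      id <- sprintf("c%04d", ci)
      fever <- logical(days); fb <- logical(days)
      cough <- logical(days); wheeze <- logical(days)
      stool <- logical(days); ear <- logical(days)

      m <- rpois(1L, episode_rate * days / 365)
      lens <- integer(0)
      if (m > 0L) {
        len_choices <- seq(length_range[1], length_range[2])
        lens <- len_choices[sample.int(length(len_choices), m, replace = TRUE)]
        # shrink the episode count until the schedule fits the follow-up window
        while (m > 0L && sum(lens) + sep * (m - 1L) > days) {
          m <- m - 1L
          lens <- lens[seq_len(m)]
        }
      }
      starts <- integer(0)
      if (m > 0L) {
        free <- days - sum(lens) - sep * (m - 1L)
        # distribute the spare free days over the m+1 gaps
        extra <- if (free > 0) as.vector(rmultinom(1L, free, rep(1, m + 1L))) else
          rep(0L, m + 1L)
        pos <- 1L
        for (k in seq_len(m)) {
          pos <- pos + extra[k] + if (k > 1L) sep else 0L
          starts <- c(starts, pos)
          pos <- pos + lens[k]
        }
        for (k in seq_len(m)) {
          idx <- starts[k]:(starts[k] + lens[k] - 1L)
          # each episode day: fever, breathing or both; force both on one day
          pick <- sample(3L, length(idx), replace = TRUE,
                         prob = c(0.35, 0.35, 0.30))
          fever[idx] <- pick != 2L
          fb[idx] <- pick != 1L
          both_day <- idx[sample.int(length(idx), 1L)]
          fever[both_day] <- TRUE; fb[both_day] <- TRUE
          # ancillary symptoms ride along on some episode days
          cough[idx] <- runif(length(idx)) < 0.4
          wheeze[idx] <- runif(length(idx)) < 0.2
        }
      }
      # isolated single-symptom noise days, kept >= 8 days from episode days
      n_noise <- rpois(1L, noise_rate * days / 365)
      if (n_noise > 0L) {
        near <- logical(days)
        for (k in seq_along(starts)) {
          lo <- max(1L, starts[k] - sep - 1L)
          hi <- min(days, starts[k] + lens[k] - 1L + sep + 1L)
          near[lo:hi] <- TRUE
        }
        eligible <- which(!near)
        n_noise <- min(n_noise, length(eligible))
        if (n_noise > 0L) {
          nd <- eligible[sample.int(length(eligible), n_noise)]
          sym <- sample(6L, n_noise, replace = TRUE)
          fever[nd[sym == 1L]] <- TRUE
          fb[nd[sym == 2L]] <- TRUE
          cough[nd[sym == 3L]] <- TRUE
          wheeze[nd[sym == 4L]] <- TRUE
          stool[nd[sym == 5L]] <- TRUE
          ear[nd[sym == 6L]] <- TRUE
        }
      }
      diaries[[ci]] <- data.frame(
        child_id = id, date = start_date + 0:(days - 1L),
        fever = fever, fast_difficult_breathing = fb,
        persistent_cough = cough, wheezing = wheeze,
        watery_stool = stool, ear_discharge = ear
      )
      if (m > 0L)
        truths[[ci]] <- data.frame(
          child_id = id,
          start_date = start_date + starts - 1L,
          end_date = start_date + starts + lens - 2L,
          n_days = lens
        )
    }
    truth <- do.call(rbind, truths)
    if (is.null(truth))
      truth <- data.frame(child_id = character(0),
                          start_date = as.Date(character(0)),
                          end_date = as.Date(character(0)),
                          n_days = integer(0))
    rownames(truth) <- NULL
    list(diary = do.call(rbind, diaries), episodes = truth)
  })
}
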