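#' Simulate a 10-second air-quality logger trace
#'
#' Generates a synthetic household logger deployment: a slowly varying
#' baseline concentration, smooth cooking-event excursions (raised-cosine
#' bumps), optional multiplicative log-normal noise, and optional isolated
#' 1-2 sample spikes emulating short-term large-particle contamination. The
#' planted cooking-event windows are returned as ground truth for round-trip
#' testing of the SIT/SIP chain.
#'
#' @param duration_h deployment length in hours (default 24; >= 18 h makes a
#'   valid daily assessment).
#' @param baseline_level baseline concentration (e.g. ug/m3 for PM2.5,
#'   ppm for CO).
#' @param n_events number of cooking events.
#' @param event_magnitude peak excess concentration of each event.
#' @param event_duration_min inclusive range of event durations in minutes
#'   (default `c(30, 90)`).
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   sample noise (default 0 = none).
#' @param baseline_drift relative amplitude of a slow sinusoidal drift of the
#'   baseline over the deployment (default 0 = constant baseline).
#' @param spike_rate expected isolated contamination spikes per hour
#'   (default 0); spikes last 1-2 samples at 10-40x the baseline level.
#' @param sample_s sampling interval in seconds (default 10).
#' @param start_time first timestamp (default 06:00 on 2011-01-01).
#' @param seed integer seed.
#' @return list with `trace` (data frame: `timestamp`, `value`,
#'   `relative_humidity`, `temperature`) and `events` (ground truth windows:
#'   `start_sample`, `end_sample`, `start_interval`, `end_interval` in
#'   10-minute interval indices).
#' @export
simulate_logger_trace <- function(duration_h = 24, baseline_level = 50,
                                  n_events = 3, event_magnitude = 500,
                                  event_duration_min = c(30, 90),
                                  noise_cv = 0, baseline_drift = 0,
                                  spike_rate = 0, sample_s = 10,
                                  start_time = as.POSIXct("2011-01-01 06:00:00",
                                                          tz = "UTC"),
                                  seed = NULL) {
  duration_h <- check_number(duration_h, "duration_h", min = 0, strict_min = TRUE)
  baseline_level <- check_number(baseline_level, "baseline_level", min = 0)
  n_events <- check_count(n_events, "n_events", min = 0L)
  event_magnitude <- check_number(event_magnitude, "event_magnitude", min = 0)
  n <- round(duration_h * 3600 / sample_s)
  per_iv <- round(600 / sample_s)

  with_seed(seed, {
    tt <- seq_len(n)
    value <- baseline_level * (1 + baseline_drift * sin(2 * pi * tt / n))
    events <- data.frame(start_sample = integer(0), end_sample = integer(0))
    if (n_events > 0L) {
      dur_choices <- seq(event_duration_min[1], event_duration_min[2])
      dur <- dur_choices[sample.int(length(dur_choices), n_events,
                                    replace = TRUE)] * 60 / sample_s
      # place events without overlap, separated by at least 30 min
      gap <- 30 * 60 / sample_s
      need <- sum(dur) + gap * (n_events - 1L)
      if (need > n) stopf("events do not fit in the deployment window")
      free <- n - need
      extra <- if (free > 0) as.vector(rmultinom(1L, free, rep(1, n_events + 1L)))
               else rep(0L, n_events + 1L)
      pos <- 1L
      starts <- integer(n_events)
      for (k in seq_len(n_events)) {
        pos <- pos + extra[k] + if (k > 1L) gap else 0L
        starts[k] <- pos
        pos <- pos + dur[k]
      }
      for (k in seq_len(n_events)) {
        idx <- starts[k]:(starts[k] + dur[k] - 1L)
        bump <- sin(pi * seq_along(idx) / length(idx))^2
        value[idx] <- value[idx] + event_magnitude * bump
      }
      events <- data.frame(start_sample = starts,
                           end_sample = as.integer(starts + dur - 1L))
    }
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      value <- value * exp(rnorm(n, -sdlog^2 / 2, sdlog))
    }
    if (spike_rate > 0) {
      n_spk <- rpois(1L, spike_rate * duration_h)
      if (n_spk > 0L) {
        at <- sample.int(n - 1L, min(n_spk, n - 1L))
        for (a in at) {
          w <- sample(1:2, 1L)
          value[a:(a + w - 1L)] <- value[a:(a + w - 1L)] +
            runif(1L, 10, 40) * max(baseline_level, 1)
        }
      }
    }
    events$start_interval <- (events$start_sample - 1L) %/% per_iv + 1L
    events$end_interval <- (events$end_sample - 1L) %/% per_iv + 1L
    trace <- data.frame(
      timestamp = start_time + (tt - 1L) * sample_s,
      value = pmax(value, 0),
      relative_humidity = 60,
      temperature = 25
    )
    list(trace = trace, events = events)
  })
}
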