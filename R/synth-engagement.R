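# Synthetic Cy5 DNA-engagement trajectories.

#' Sample a ground-truth DNA-engagement event sequence
#'
#' Draws the underlying event process of [gen_engagement_trajectory()]
#' without rendering an intensity trace: quiescent gaps from the
#' two-component exponential mixture, intrinsic engagement lifetimes from the
#' three-component mixture, and an independent exponential photobleaching
#' clock per engagement. The observed end of each engagement is the earlier
#' of dissociation (intrinsic lifetime) and photobleaching; events running
#' past `duration` are truncated and marked `censored_at_trace_end`.
#'
#' Gaps are drawn by direct mixture sampling (the mixture is the observable
#' fitted downstream); the component drawn for each gap is recorded as
#' `gap_component` metadata with its quiescent/engaging-state reading.
#'
#' @param kinetics An [engagement_kinetics()] object.
#' @param duration Observation time, seconds.
#' @param seed Optional RNG seed.
#' @return Tibble with one row per engagement: `start_s`, `end_s`,
#'   `lifetime_s` (observed), `intrinsic_lifetime_s`, `class`, `end_reason`,
#'   `gap_before_s`, `gap_component` (`"short"`/`"long"`),
#'   `lifetime_component`.
#' @export
sample_engagement_events <- function(kinetics, duration, seed = NULL) {
  stopifnot(inherits(kinetics, "engagement_kinetics"))
  if (!is.numeric(duration) || duration <= 0) abort("`duration` must be > 0.")
  local_seed_if(seed)

  start <- numeric(0); end <- numeric(0); gap <- numeric(0)
  gap_comp <- character(0); life_comp <- integer(0)
  intrinsic <- numeric(0); reason <- character(0)

  t <- 0
  repeat {
    long_gap <- stats::runif(1) < kinetics$amp_long
    g <- stats::rexp(1, rate = 1 / if (long_gap) kinetics$tau_long else kinetics$tau_short)
    s <- t + g
    if (s >= duration) break
    comp <- sample.int(3L, 1L, prob = kinetics$lifetime_weights)
    life <- stats::rexp(1, rate = 1 / kinetics$lifetime_taus[comp])
    bleach <- stats::rexp(1, rate = 1 / kinetics$bleach_lifetime)
    obs_end <- s + min(life, bleach)
    if (obs_end > duration) {
      start <- c(start, s); end <- c(end, duration); gap <- c(gap, g)
      gap_comp <- c(gap_comp, if (long_gap) "long" else "short")
      life_comp <- c(life_comp, comp); intrinsic <- c(intrinsic, life)
      reason <- c(reason, "censored_at_trace_end")
      break
    }
    start <- c(start, s); end <- c(end, obs_end); gap <- c(gap, g)
    gap_comp <- c(gap_comp, if (long_gap) "long" else "short")
    life_comp <- c(life_comp, comp); intrinsic <- c(intrinsic, life)
    reason <- c(reason, if (bleach < life) "photobleach" else "dissociation")
    t <- obs_end
  }

  tibble(
    start_s = start,
    end_s = end,
    lifetime_s = end - start,
    intrinsic_lifetime_s = intrinsic,
    class = classify_engagement(end - start),
    end_reason = reason,
    gap_before_s = gap,
    gap_component = gap_comp,
    lifetime_component = life_comp
  )
}

#' Generate Cy5 engagement intensity trajectories
#'
#' Renders intensity traces from the event process of
#' [sample_engagement_events()]: baseline 0 a.u., plus `spike_amplitude`
#' while a DNA molecule is engaged, plus i.i.d. Gaussian noise per frame.
#'
#' @inheritParams sample_engagement_events
#' @param n_traces Number of independent motors/trajectories.
#' @param spike_amplitude Intensity of an engagement spike, a.u. (> 0).
#' @param noise_sd Gaussian noise s.d., a.u.
#' @param frame_interval Sampling interval, seconds (default 0.1 s).
#' @return A list of class `engagement_sim` with `traces` (long tibble:
#'   `trace_id`, `time_s`, `intensity_au`, `channel = "Cy5"`) and `events`
#'   (ground truth per engagement, with `trace_id`).
#' @export
gen_engagement_trajectory <- function(kinetics, duration = 240,
                                      spike_amplitude = 1, noise_sd = 1 / 3,
                                      frame_interval = 0.1, n_traces = 1,
                                      seed = NULL) {
  stopifnot(inherits(kinetics, "engagement_kinetics"))
  if (!is.numeric(duration) || duration <= 0) abort("`duration` must be > 0.")
  if (!is.numeric(spike_amplitude) || spike_amplitude <= 0) {
    abort("`spike_amplitude` must be > 0.")
  }
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  check_positive(frame_interval, "frame_interval")
  n_traces <- check_count(n_traces, "n_traces")
  local_seed_if(seed)

  times <- seq(0, duration - frame_interval / 2, by = frame_interval)
  n_frames <- length(times)

  event_list <- vector("list", n_traces)
  intensity <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    ev <- sample_engagement_events(kinetics, duration)
    event_list[[i]] <- ev
    engaged <- rep(FALSE, n_frames)
    for (j in seq_len(nrow(ev))) {
      engaged[times >= ev$start_s[j] & times < ev$end_s[j]] <- TRUE
    }
    intensity[[i]] <- engaged * spike_amplitude +
      if (noise_sd > 0) stats::rnorm(n_frames, sd = noise_sd) else 0
  }

  traces <- tibble(
    trace_id = rep(seq_len(n_traces), each = n_frames),
    time_s = rep(times, n_traces),
    intensity_au = unlist(intensity),
    channel = "Cy5"
  )
  events <- dplyr::bind_rows(event_list, .id = "trace_id") |>
    dplyr::mutate(trace_id = as.integer(.data$trace_id), .before = 1L)
  structure(list(traces = traces, events = events), class = "engagement_sim")
}
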