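# Packaging-dynamics analysis of constant-force extension traces: rolling
# velocity, pause detection/classification, and per-trace metrics.

#' Rolling-window packaging velocity
#'
#' Converts the extension trace to unpackaged base pairs via the worm-like
#' chain at the trace force, then takes the slope of an ordinary
#' least-squares line over a centered running window (default 0.1 s).
#' Sign convention: packaging (extension decreasing) is positive.
#'
#' @param trace Tibble with `time_s`, `extension_nm` and `force_pN`
#'   (constant), uniformly sampled.
#' @param window Window length, seconds; must cover at least 2 frames.
#' @param params A [wlc_params()] object for the bp conversion.
#' @return Tibble `time_s`, `bp_unpackaged`, `velocity_bp_s` (NA within half
#'   a window of the trace ends).
#' @export
rolling_velocity <- function(trace, window = 0.1, params = wlc_params()) {
  tms <- trace$time_s
  if (is.null(tms) || is.null(trace$extension_nm)) {
    abort("`trace` needs `time_s` and `extension_nm`.")
  }
  dt <- stats::median(diff(tms))
  h <- floor(window / dt / 2)
  if (2L * h + 1L < 2L || length(tms) < 2L * h + 1L) {
    abort("Trace shorter than the velocity window.")
  }
  force <- trace$force_pN[1]
  bp <- bp_from_extension(pmax(trace$extension_nm, 0), force, params)
  j <- h:(-h)
  coefs <- j / (sum(j^2) * dt)
  slope <- stats::filter(bp, coefs, sides = 2)
  tibble(
    time_s = tms,
    bp_unpackaged = bp,
    velocity_bp_s = -as.numeric(slope) # packaging positive
  )
}

#' Detect pauses in a velocity series
#'
#' Assigns a velocity threshold from the variance of the velocity series
#' (`threshold = max(v_floor, median(v) - c_mad * mad(v))`, computed over the
#' packaging mode), marks frames below it as potential pauses, and records
#' maximal below-threshold intervals as pauses when they outlast
#' `min_duration` (default 0.1 s) plus half the rolling-velocity window: the
#' window smears a physical stall of duration `d` into a below-threshold
#' excursion of roughly `d + window / 2`, so the allowance keeps stalls at or
#' below `min_duration` from being reported. The mean velocity within each
#' interval (trimmed of half a window at each end, where boundary smearing
#' mixes in packaging frames) is reported for classification.
#'
#' @param velocity Tibble from [rolling_velocity()].
#' @param threshold Numeric threshold in bp/s, or `"variance"` for the rule
#'   above.
#' @param min_duration Seconds; a pause must outlast this.
#' @param window Rolling-velocity window length, seconds (must match the
#'   value used in [rolling_velocity()]).
#' @param v_floor,c_mad Parameters of the variance rule. Defaults are
#'   calibrated on synthetic traces so that pause-free traces at realistic
#'   signal-to-noise yield at most ~0.1 false pauses per trace.
#' @return Tibble of pauses: `start_s`, `end_s`, `duration_s`,
#'   `pause_velocity_bp_s`, `n_frames`, with the threshold used attached as
#'   attribute `"threshold"`.
#' @export
detect_pauses <- function(velocity, threshold = "variance",
                          min_duration = 0.1, window = 0.1, v_floor = 25,
                          c_mad = 3) {
  v <- velocity$velocity_bp_s
  tms <- velocity$time_s
  if (identical(threshold, "variance")) {
    vv <- v[!is.na(v)]
    # centre the rule on the packaging mode, in two stages: pause-dominated
    # points would otherwise drag the median down and inflate the MAD until
    # the threshold collapses on pause-heavy traces
    vp <- vv[vv > v_floor]
    if (length(vp) < 10L) vp <- vv
    m1 <- stats::median(vp)
    vp2 <- vv[vv > 0.5 * m1]
    if (length(vp2) >= 10L) vp <- vp2
    threshold <- max(v_floor, stats::median(vp) - c_mad * stats::mad(vp))
  }
  dt <- stats::median(diff(tms))
  h <- max(1L, floor(window / dt / 2))
  below <- !is.na(v) & v < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * dt) > min_duration + window / 2
  pv <- vapply(which(keep), function(i) {
    s <- starts[i]; e <- ends[i]
    if (e - s + 1L > 2L * h + 2L) { s <- s + h; e <- e - h }
    mean(v[s:e])
  }, numeric(1))
  out <- tibble(
    start_s = tms[starts[keep]],
    end_s = tms[ends[keep]] + dt,
    duration_s = (r$lengths[keep]) * dt,
    pause_velocity_bp_s = pv,
    n_frames = r$lengths[keep]
  )
  attr(out, "threshold") <- threshold
  out
}

#' Classify a pause as plateau or unpackaging
#'
#' Pauses with mean velocity within `plateau_band` of zero are plateaus
#' (packaging stopped); pauses with velocity below `-plateau_band` are
#' unpackaging events (gradual DNA release, observed at roughly -100 to
#' -500 bp/s). A pause velocity above `+plateau_band` should not occur by
#' construction and is flagged.
#'
#' @param pause_velocity Mean velocity within the pause, bp/s; vectorized.
#' @param plateau_band Half-width of the plateau band, bp/s.
#' @return Character vector: `"plateau"`, `"unpackaging"`, or
#'   `"contradiction"` (with a warning).
#' @export
classify_pause <- function(pause_velocity, plateau_band = 50) {
  check_positive(plateau_band, "plateau_band")
  out <- ifelse(abs(pause_velocity) <= plateau_band, "plateau",
                ifelse(pause_velocity < -plateau_band, "unpackaging",
                       "contradiction"))
  if (any(out == "contradiction")) {
    warn("Pause with velocity above the plateau band: should not occur for detected pauses.")
  }
  out
}

#' Per-trace packaging metrics
#'
#' Computes the paper-style summary of one packaging trace: the pauses are
#' excised, the remaining packaging intervals are catenated, and the
#' pause-free velocity is the total base pairs packaged during packaging
#' intervals divided by the total packaging time. Pause frequency is the
#' number of pauses per kb packaged; the start time is the elapsed time from
#' `t0_atp_entry` to the first packaging instant (the end of an initial
#' non-packaging interval, which is not counted as a pause).
#'
#' @param trace Extension trace tibble (`time_s`, `extension_nm`,
#'   `force_pN`).
#' @param pauses Pause tibble from [detect_pauses()] (or generator ground
#'   truth with `start_s`/`end_s`).
#' @param t0_atp_entry Time origin for the start time, seconds.
#' @param window Velocity window used for bp smoothing, seconds.
#' @param params A [wlc_params()] object.
#' @return One-row tibble: `start_time_s`, `pause_free_velocity_bp_s`,
#'   `pause_frequency_per_kb`, `mean_pause_duration_s` (NA when no pauses),
#'   `total_packaged_bp`, `n_pauses`.
#' @export
trace_metrics <- function(trace, pauses, t0_atp_entry = 0, window = 0.1,
                          params = wlc_params()) {
  tms <- trace$time_s
  dt <- stats::median(diff(tms))
  force <- trace$force_pN[1]
  bp <- bp_from_extension(pmax(trace$extension_nm, 0), force, params)
  h <- max(1L, floor(window / dt / 2))
  bp_s <- stats::filter(bp, rep(1 / (2 * h + 1), 2 * h + 1), sides = 2)
  bp_s <- as.numeric(bp_s)
  # fill smoothing edges with raw values
  bp_s[is.na(bp_s)] <- bp[is.na(bp_s)]

  in_pause <- rep(FALSE, length(tms))
  for (i in seq_len(nrow(pauses))) {
    in_pause[tms >= pauses$start_s[i] & tms < pauses$end_s[i]] <- TRUE
  }

  # a non-packaging interval at the very start of the trace is the start
  # delay (waiting for the first packaging), not a pause
  start_time <- tms[1] - t0_atp_entry
  keep_pause <- rep(TRUE, nrow(pauses))
  if (nrow(pauses) > 0) {
    first_p <- which.min(pauses$start_s)
    if (pauses$start_s[first_p] <= tms[1] + window) {
      start_time <- pauses$end_s[first_p] - t0_atp_entry
      keep_pause[first_p] <- FALSE
    }
  }
  start_idx <- which(tms >= start_time + t0_atp_entry)[1]
  if (is.na(start_idx)) abort("Metrics undefined: trace never packages.")

  pack <- seq_along(tms) >= start_idx & !in_pause
  # packaging intervals; a half-window guard is trimmed at boundaries
  # adjacent to pauses so that velocity smearing across the pause edge does
  # not bias the catenated pause-free velocity
  r <- rle(pack)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ki <- which(r$values)
  d_bp <- 0; d_t <- 0; tot_bp <- 0
  for (i in ki) {
    s <- starts[i]; e <- ends[i]
    tot_bp <- tot_bp + (bp_s[s] - bp_s[e])
    if (s > 1L) s <- s + h
    if (e < length(tms)) e <- e - h
    if (e - s < 2L) next
    d_bp <- d_bp + (bp_s[s] - bp_s[e])
    d_t <- d_t + (tms[e] - tms[s])
  }
  if (d_bp <= 0 || d_t <= 0) abort("Metrics undefined: no net packaging detected.")

  n_pauses <- sum(keep_pause)
  tibble(
    start_time_s = start_time,
    pause_free_velocity_bp_s = d_bp / d_t,
    pause_frequency_per_kb = n_pauses / (tot_bp / 1000),
    mean_pause_duration_s = if (n_pauses > 0) mean(pauses$duration_s[keep_pause]) else NA_real_,
    total_packaged_bp = tot_bp,
    n_pauses = n_pauses
  )
}
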