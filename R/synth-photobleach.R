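# Synthetic motor compositions and Cy3 photobleaching traces.

#' Sample hetero-pentamer motor compositions from a doped subunit pool
#'
#' Each of the `n_subunits` positions of each motor is independently inactive
#' with probability `doping_fraction`, so the per-motor inactive count is
#' binomial — the random-assembly model behind the composition pmf.
#'
#' @param n_motors Number of motors to draw.
#' @param doping_fraction Molar fraction of inactive monomers in the pool.
#' @param n_subunits Ring size (default 5).
#' @param labeled_role Which species carries the fluorescent label:
#'   `"active"` (wild-type subunits labeled, the stoichiometry experiment) or
#'   `"inactive"` (only the ATPase-dead subunits labeled, the
#'   inactive-subunit-counting experiment).
#' @param label_prob Per-subunit labeling probability of the labeled species.
#' @param seed Optional RNG seed for reproducibility.
#' @return Tibble with one row per motor: `motor_id`, `n_subunits`,
#'   `n_inactive`, `labeled_role`, `per_subunit_label_prob`.
#' @examples
#' sample_motor_composition(5, doping_fraction = 0.5, seed = 1)
#' @export
sample_motor_composition <- function(n_motors, doping_fraction,
                                     n_subunits = 5,
                                     labeled_role = c("active", "inactive"),
                                     label_prob = 1, seed = NULL) {
  n_motors <- check_count(n_motors, "n_motors")
  check_probability(doping_fraction, "doping_fraction")
  check_probability(label_prob, "label_prob")
  n <- check_count(n_subunits, "n_subunits")
  labeled_role <- match.arg(labeled_role)
  local_seed_if(seed)
  tibble(
    motor_id = seq_len(n_motors),
    n_subunits = n,
    n_inactive = stats::rbinom(n_motors, n, doping_fraction),
    labeled_role = labeled_role,
    per_subunit_label_prob = label_prob
  )
}

#' Generate Cy3 photobleaching intensity traces
#'
#' For each motor composition, the number of fluorescent labels is drawn
#' binomially from the labeled species (active or inactive subunits) with the
#' per-subunit labeling probability; each label photobleaches at an
#' independent exponential time. The noiseless trace is a non-increasing
#' staircase starting at `true_label_count * step_amplitude` over a zero
#' baseline, to which i.i.d. Gaussian noise is added. Motors with zero labels
#' produce flat noise-only traces and are flagged undetectable (in a real
#' experiment no spot would be picked up).
#'
#' @param compositions Tibble from [sample_motor_composition()] (or any data
#'   frame with `motor_id`, `n_subunits`, `n_inactive`, `labeled_role`,
#'   `per_subunit_label_prob`).
#' @param step_amplitude Intensity drop per bleaching step, a.u. (> 0).
#' @param bleach_mean Mean photobleaching time per label, seconds.
#' @param noise_sd Gaussian noise s.d., a.u. The default gives a 3:1
#'   step-amplitude-to-noise ratio.
#' @param duration Trace length, seconds.
#' @param frame_interval Sampling interval, seconds (default 0.1 s).
#' @param seed Optional RNG seed.
#' @return A list of class `photobleach_sim` with elements
#'   \describe{
#'     \item{traces}{long tibble: `trace_id`, `time_s`, `intensity_au`,
#'       `channel` (`"Cy3"`).}
#'     \item{truth}{per-trace ground truth: `trace_id`, `true_label_count`,
#'       `n_inactive`, `detectable`, and `step_times` (list column of bleach
#'       times, seconds).}
#'   }
#' @export
gen_photobleach_traces <- function(compositions, step_amplitude = 1,
                                   bleach_mean = 8, noise_sd = 1 / 3,
                                   duration = 60, frame_interval = 0.1,
                                   seed = NULL) {
  if (duration <= 0) abort("`duration` must be > 0.")
  check_positive(step_amplitude, "step_amplitude")
  check_positive(bleach_mean, "bleach_mean")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  check_positive(frame_interval, "frame_interval")
  local_seed_if(seed)

  times <- seq(0, duration - frame_interval / 2, by = frame_interval)
  n_frames <- length(times)
  n_traces <- nrow(compositions)

  n_labeled_pool <- ifelse(compositions$labeled_role == "inactive",
                           compositions$n_inactive,
                           compositions$n_subunits - compositions$n_inactive)
  label_counts <- stats::rbinom(n_traces, n_labeled_pool,
                                compositions$per_subunit_label_prob)

  step_times <- vector("list", n_traces)
  intensity <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    k <- label_counts[i]
    bleach <- sort(stats::rexp(k, rate = 1 / bleach_mean))
    step_times[[i]] <- bleach
    surviving <- if (k > 0) {
      # labels still fluorescent at each frame
      k - findInterval(times, bleach)
    } else {
      rep(0L, n_frames)
    }
    intensity[[i]] <- surviving * step_amplitude +
      if (noise_sd > 0) stats::rnorm(n_frames, sd = noise_sd) else 0
  }

  traces <- tibble(
    trace_id = rep(seq_len(n_traces), each = n_frames),
    time_s = rep(times, n_traces),
    intensity_au = unlist(intensity),
    channel = "Cy3"
  )
  truth <- tibble(
    trace_id = seq_len(n_traces),
    true_label_count = label_counts,
    n_inactive = compositions$n_inactive,
    detectable = label_counts > 0L,
    step_times = step_times
  )
  structure(list(traces = traces, truth = truth), class = "photobleach_sim")
}
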