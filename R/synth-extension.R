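# Synthetic optical-trap extension traces under constant force.

#' Generate a constant-force DNA-extension packaging trace
#'
#' Simulates packaging of a DNA tether at constant force: the motor packages
#' at the injected pause-free velocity, interrupted by pauses placed as a
#' homogeneous Poisson process in packaged length (matching the
#' pauses-per-kb statistic). A pause is either a plateau (velocity 0) or,
#' with probability `unpackaging_fraction`, a gradual release of DNA at
#' `unpackaging_velocity`. Unpackaged base pairs are converted to extension
#' via the extensible worm-like chain at the trace force, and i.i.d.
#' Gaussian noise (nm) is added per frame.
#'
#' If an unpackaging pause releases more DNA than has been packaged, the
#' tether is fully unpackaged; the trace is truncated there and flagged as a
#' failure.
#'
#' @param params A [trap_sim_params()] object.
#' @param wlc A [wlc_params()] object; its contour length is ignored in
#'   favour of `params$dna_length * rise_per_bp`.
#' @param n_traces Number of traces.
#' @param seed Optional RNG seed.
#' @return A list of class `extension_sim`:
#'   \describe{
#'     \item{traces}{`trace_id`, `time_s`, `extension_nm`, `force_pN`, and
#'       the noise-free ground truth `bp_unpackaged_true`.}
#'     \item{pauses}{ground-truth pause annotation: `trace_id`, `start_s`,
#'       `end_s`, `duration_s`, `pause_type`, `pause_velocity_bp_s`.}
#'     \item{truth}{per-trace: injected `pause_free_velocity`,
#'       `start_delay_s`, `total_packaged_bp`, `n_pauses`, `failed`.}
#'   }
#' @export
gen_extension_trace <- function(params, wlc = wlc_params(), n_traces = 1,
                                seed = NULL) {
  stopifnot(inherits(params, "trap_sim_params"), inherits(wlc, "wlc_params"))
  n_traces <- check_count(n_traces, "n_traces")
  local_seed_if(seed)

  rel <- wlc_relative_extension(params$force, wlc)
  nm_per_bp <- wlc$rise_per_bp * rel
  v <- params$pause_free_velocity

  trace_list <- vector("list", n_traces)
  pause_list <- vector("list", n_traces)
  truth_list <- vector("list", n_traces)

  for (i in seq_len(n_traces)) {
    # pause positions along packaged length, homogeneous Poisson per bp
    pos <- if (params$pause_rate > 0) {
      p <- cumsum(stats::rexp(
        ceiling(params$dna_length * params$pause_rate / 1000 * 4) + 10,
        rate = params$pause_rate / 1000
      ))
      p[p < params$dna_length]
    } else {
      numeric(0)
    }

    # piecewise-linear trajectory in (time, packaged bp)
    bt <- 0; bp <- 0                      # breakpoint accumulators
    times_br <- 0; packed_br <- 0
    if (params$start_delay_s > 0) {
      bt <- params$start_delay_s
      times_br <- c(times_br, bt); packed_br <- c(packed_br, 0)
    }
    p_start <- numeric(0); p_end <- numeric(0)
    p_type <- character(0); p_vel <- numeric(0)
    failed <- FALSE
    for (pp in c(pos, params$dna_length)) {
      seg <- pp - bp
      bt <- bt + seg / v; bp <- pp
      times_br <- c(times_br, bt); packed_br <- c(packed_br, bp)
      if (pp >= params$dna_length) break
      d <- stats::rexp(1, rate = 1 / params$pause_duration_mean)
      unpack <- stats::runif(1) < params$unpackaging_fraction &&
        params$unpackaging_velocity < 0
      pv <- if (unpack) params$unpackaging_velocity else 0
      bp_new <- bp + pv * d
      if (bp_new < 0) {
        # DNA fully released: truncate at the moment packaged length hits 0
        d <- bp / abs(pv); bp_new <- 0; failed <- TRUE
      }
      p_start <- c(p_start, bt); p_end <- c(p_end, bt + d)
      p_type <- c(p_type, if (unpack) "unpackaging" else "plateau")
      p_vel <- c(p_vel, pv)
      bt <- bt + d; bp <- bp_new
      times_br <- c(times_br, bt); packed_br <- c(packed_br, bp)
      if (failed) break
    }

    t_grid <- seq(0, bt, by = params$frame_interval)
    packed <- stats::approx(times_br, packed_br, xout = t_grid)$y
    bp_unpack <- params$dna_length - packed
    ext <- bp_unpack * nm_per_bp +
      if (params$noise_sd > 0) stats::rnorm(length(t_grid), sd = params$noise_sd) else 0

    trace_list[[i]] <- tibble(
      trace_id = i, time_s = t_grid, extension_nm = ext,
      force_pN = params$force, bp_unpackaged_true = bp_unpack
    )
    pause_list[[i]] <- tibble(
      trace_id = i, start_s = p_start, end_s = p_end,
      duration_s = p_end - p_start, pause_type = p_type,
      pause_velocity_bp_s = p_vel
    )
    truth_list[[i]] <- tibble(
      trace_id = i, pause_free_velocity = v,
      start_delay_s = params$start_delay_s,
      total_packaged_bp = max(packed_br), n_pauses = length(p_start),
      failed = failed
    )
  }

  structure(
    list(
      traces = dplyr::bind_rows(trace_list),
      pauses = dplyr::bind_rows(pause_list),
      truth = dplyr::bind_rows(truth_list)
    ),
    class = "extension_sim"
  )
}
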