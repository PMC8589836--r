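# Gillespie kinetic Monte Carlo simulation of DNA packaging as a 1-D walk.
#
# The motor either packages `step_size` bp (a controlled, ATP-driven event)
# or pauses-and-slips, releasing an exponentially distributed length of DNA
# (an uncontrolled event). Event times are exponential with separate means
# for the two event types; the trajectory succeeds when the unpackaged
# length reaches 0 and fails when it exceeds the DNA length (the tether
# slips out entirely).
#
# Two readings of the inactive-subunit rule are provided:
#  * "effective" (default): the pause&slip probability is a condition-level
#    parameter already reflecting the motor's inactive-subunit content (the
#    walk is homogeneous); a fully inactive motor (n_inactive = n) can never
#    package and always fails.
#  * "per_position": a grip pointer rotates around the ring (advancing after
#    every event or only after packaging events); whenever it sits on an
#    inactive subunit the packaging probability is 0 and the motor
#    pauses-and-slips with certainty.
# The per-position reading with condition-level p values of 0.65/0.75 gives
# zero or negative per-event drift for doped motors (see
# `kmc_expected_drift()`), so sustained packaging by doped motors — and a
# finite velocity ratio — arises only under the effective reading, which is
# therefore the default.

#' Kinetic Monte Carlo simulation parameters
#'
#' Defaults are the standard packaging-simulation conditions: a pentamer
#' packaging 3400 bp of which 30-40 bp (uniform) are pre-packaged, 2-bp
#' packaging steps, exponential slip lengths with mean 0.5 bp, mean event
#' times of 10 (package) and 2 (pause&slip) arbitrary units, and
#' p_pause&slip of 0.65 for an all-active motor (0.75 is the corresponding
#' doped-motor value).
#'
#' @param n_subunits Ring size.
#' @param n_inactive Number of ATPase-dead subunits, `0..n_subunits`.
#' @param p_pause_slip Probability that an event is a pause&slip rather than
#'   a packaging step (at active grip positions under the per-position
#'   rule; unconditionally under the effective rule).
#' @param slip_mean Mean slip length, bp.
#' @param t_package_mean,t_pause_slip_mean Mean event durations, arbitrary
#'   time units.
#' @param dna_length Tether length, bp.
#' @param pre_packaged Length-2 range (bp) of pre-packaged DNA, drawn
#'   uniformly per trajectory (or a single fixed value).
#' @param step_size Packaging step, bp.
#' @param inactive_rule `"effective"` or `"per_position"` (see Details).
#' @param inactive_placement `"random"` ring positions per trajectory, or
#'   `"specified"` via `inactive_positions`.
#' @param inactive_positions Integer ring positions of the inactive
#'   subunits when placement is `"specified"`.
#' @param grip_advance Grip-pointer policy for the per-position rule:
#'   advance after `"every_event"` (default) or `"on_package_only"`.
#' @param slip_rounding `"continuous"` exponential slip lengths (default)
#'   or `"round"` to integer bp.
#' @param scheme `"flexible_bypass"` (inactive subunits are slipped past)
#'   or `"strict_arrest"` (the motor arrests permanently when the grip
#'   pointer reaches an inactive subunit).
#' @param max_events Event cap per trajectory; trajectories hitting it are
#'   flagged `censored`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subunits = 5, n_inactive = 0, p_pause_slip = 0.65,
                       slip_mean = 0.5, t_package_mean = 10,
                       t_pause_slip_mean = 2, dna_length = 3400,
                       pre_packaged = c(30, 40), step_size = 2,
                       inactive_rule = c("effective", "per_position"),
                       inactive_placement = c("random", "specified"),
                       inactive_positions = NULL,
                       grip_advance = c("every_event", "on_package_only"),
                       slip_rounding = c("continuous", "round"),
                       scheme = c("flexible_bypass", "strict_arrest"),
                       max_events = 1e6) {
  n_subunits <- check_count(n_subunits, "n_subunits")
  n_inactive <- check_count(n_inactive, "n_inactive")
  if (n_inactive > n_subunits) abort("`n_inactive` must be <= `n_subunits`.")
  check_probability(p_pause_slip, "p_pause_slip")
  check_positive(c(slip_mean, t_package_mean, t_pause_slip_mean, dna_length,
                   step_size, max_events), "rate/size parameters")
  if (length(pre_packaged) == 1L) pre_packaged <- rep(pre_packaged, 2L)
  if (any(pre_packaged < 0) || any(pre_packaged >= dna_length) ||
      pre_packaged[2] < pre_packaged[1]) {
    abort("`pre_packaged` must be a valid range within [0, dna_length).")
  }
  inactive_rule <- match.arg(inactive_rule)
  inactive_placement <- match.arg(inactive_placement)
  grip_advance <- match.arg(grip_advance)
  slip_rounding <- match.arg(slip_rounding)
  scheme <- match.arg(scheme)
  if (inactive_placement == "specified") {
    inactive_positions <- check_count(inactive_positions, "inactive_positions")
    if (length(inactive_positions) != n_inactive ||
        any(inactive_positions < 1 | inactive_positions > n_subunits)) {
      abort("`inactive_positions` must be `n_inactive` distinct ring positions.")
    }
  }
  structure(
    list(n_subunits = n_subunits, n_inactive = n_inactive,
         p_pause_slip = p_pause_slip, slip_mean = slip_mean,
         t_package_mean = t_package_mean,
         t_pause_slip_mean = t_pause_slip_mean, dna_length = dna_length,
         pre_packaged = pre_packaged, step_size = step_size,
         inactive_rule = inactive_rule,
         inactive_placement = inactive_placement,
         inactive_positions = inactive_positions,
         grip_advance = grip_advance, slip_rounding = slip_rounding,
         scheme = scheme, max_events = max_events),
    class = "sim_config"
  )
}

#' Closed-form per-event drift of the packaging walk
#'
#' Expected change in packaged length per event, together with the expected
#' event duration and the resulting asymptotic velocity, for a given
#' configuration. Under the per-position rule with the grip advancing every
#' event, a fraction `n_inactive / n_subunits` of events occur at inactive
#' positions and are forced slips.
#'
#' @param config A [sim_config()] object.
#' @return One-row tibble: `drift_bp_per_event`, `mean_event_time`,
#'   `velocity_bp_per_time`.
#' @export
kmc_expected_drift <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$p_pause_slip
  mu <- config$slip_mean
  if (config$slip_rounding == "round") {
    # E[round(X)] for X ~ Exp(mean mu): sum_{k>=1} k P(round(X)=k)
    kk <- 0:200
    mu <- sum(kk * (exp(-pmax(kk - 0.5, 0) / config$slip_mean) -
                      exp(-(kk + 0.5) / config$slip_mean)))
  }
  phi <- switch(config$inactive_rule,
    effective = if (config$n_inactive == config$n_subunits) 1 else 0,
    per_position = config$n_inactive / config$n_subunits
  )
  s <- config$step_size
  drift <- (1 - phi) * ((1 - p) * s - p * mu) + phi * (-mu)
  tmean <- (1 - phi) * ((1 - p) * config$t_package_mean +
                          p * config$t_pause_slip_mean) +
    phi * config$t_pause_slip_mean
  tibble(drift_bp_per_event = drift, mean_event_time = tmean,
         velocity_bp_per_time = drift / tmean)
}

# simulate one trajectory; chunked vectorized sampling
run_one_trajectory <- function(cfg, keep_trajectory = FALSE) {
  n <- cfg$n_subunits
  inactive <- rep(FALSE, n)
  if (cfg$n_inactive > 0) {
    pos <- if (cfg$inactive_placement == "specified") {
      cfg$inactive_positions
    } else {
      sample.int(n, cfg$n_inactive)
    }
    inactive[pos] <- TRUE
  }
  pre <- stats::runif(1, cfg$pre_packaged[1], cfg$pre_packaged[2])
  u0 <- cfg$dna_length - pre
  start_pos <- sample.int(n, 1L)

  per_pos <- cfg$inactive_rule == "per_position"
  strict <- cfg$scheme == "strict_arrest"
  loop_mode <- cfg$grip_advance == "on_package_only" && (per_pos || strict)

  u <- u0; t_tot <- 0; ev <- 0L; n_slip <- 0L
  traj_u <- if (keep_trajectory) u0 else NULL
  traj_t <- if (keep_trajectory) 0 else NULL
  outcome <- NA_character_

  if (loop_mode) {
    # grip advances only after packaging events: outcome-dependent pointer,
    # simulated event by event
    ptr <- start_pos
    while (ev < cfg$max_events) {
      ev <- ev + 1L
      on_inactive <- inactive[ptr]
      if (strict && on_inactive) { outcome <- "failure"; break }
      p_slip <- if (per_pos && on_inactive) 1 else cfg$p_pause_slip
      slip <- stats::runif(1) < p_slip
      if (slip) {
        len <- stats::rexp(1, 1 / cfg$slip_mean)
        if (cfg$slip_rounding == "round") len <- round(len)
        u <- u + len; n_slip <- n_slip + 1L
        t_tot <- t_tot + stats::rexp(1, 1 / cfg$t_pause_slip_mean)
      } else {
        u <- u - cfg$step_size
        t_tot <- t_tot + stats::rexp(1, 1 / cfg$t_package_mean)
        ptr <- ptr %% n + 1L
      }
      if (keep_trajectory) { traj_u <- c(traj_u, u); traj_t <- c(traj_t, t_tot) }
      if (u <= 0) { outcome <- "success"; break }
      if (u > cfg$dna_length) { outcome <- "failure"; break }
    }
  } else {
    # grip position after every event is deterministic, so events can be
    # sampled in vectorized chunks
    chunk <- 16384L
    repeat {
      m <- as.integer(min(chunk, cfg$max_events - ev))
      if (m <= 0L) break
      if (per_pos || strict) {
        posv <- ((start_pos - 1L + ev + seq_len(m) - 1L) %% n) + 1L
        on_inactive <- inactive[posv]
      } else {
        on_inactive <- rep(FALSE, m)
      }
      arrest_at <- if (strict && any(on_inactive)) which(on_inactive)[1] else Inf
      p_slip <- if (per_pos) {
        ifelse(on_inactive, 1, cfg$p_pause_slip)
      } else if (cfg$n_inactive == n) 1 else cfg$p_pause_slip
      slip <- stats::runif(m) < p_slip
      len <- stats::rexp(m, 1 / cfg$slip_mean)
      if (cfg$slip_rounding == "round") len <- round(len)
      d <- ifelse(slip, len, -cfg$step_size)
      tt <- stats::rexp(m, 1 / ifelse(slip, cfg$t_pause_slip_mean,
                                      cfg$t_package_mean))
      cu <- u + cumsum(d)
      ct <- t_tot + cumsum(tt)
      hit0 <- which(cu <= 0)
      hitL <- which(cu > cfg$dna_length)
      k0 <- if (length(hit0)) hit0[1] else Inf
      kL <- if (length(hitL)) hitL[1] else Inf
      if (is.finite(arrest_at) && arrest_at <= min(k0, kL)) {
        # arrest pre-empts the event at the inactive position
        take <- as.integer(arrest_at) - 1L
        outcome <- "failure"
      } else if (is.finite(min(k0, kL))) {
        take <- as.integer(min(k0, kL))
        outcome <- if (k0 < kL) "success" else "failure"
      } else {
        take <- m
      }
      if (take > 0L) {
        if (keep_trajectory) {
          traj_u <- c(traj_u, cu[seq_len(take)])
          traj_t <- c(traj_t, ct[seq_len(take)])
        }
        u <- cu[take]
        t_tot <- ct[take]
        n_slip <- n_slip + sum(slip[seq_len(take)])
      }
      ev <- ev + if (!is.na(outcome) && outcome == "failure" &&
                       arrest_at <= min(k0, kL)) take + 1L else take
      if (!is.na(outcome)) break
    }
  }
  if (is.na(outcome)) outcome <- "censored"

  list(
    outcome = outcome, pre_packaged = pre, unpackaged_final = u,
    completion_time = t_tot, n_events = ev, n_slip_events = n_slip,
    mean_velocity = (u0 - u) / max(t_tot, .Machine$double.eps),
    trajectory = if (keep_trajectory) {
      tibble(time = traj_t, unpackaged_bp = traj_u)
    } else {
      NULL
    }
  )
}

#' Simulate packaging trajectories
#'
#' Runs the kinetic Monte Carlo packaging walk for `n_traj` independent
#' motors under one configuration. Identical `config` and `seed` give
#' bit-identical results.
#'
#' @param config A [sim_config()] object.
#' @param n_traj Number of trajectories.
#' @param seed Optional RNG seed.
#' @param keep_trajectory Record the full (time, unpackaged length)
#'   trajectory per run (list column; memory-heavy for long walks).
#' @return Tibble with one row per trajectory: `traj_id`, `outcome`
#'   (`success`/`failure`/`censored`), `pre_packaged_bp`,
#'   `unpackaged_final_bp`, `completion_time`, `n_events`, `n_slip_events`,
#'   `mean_velocity` (net packaged bp per arbitrary time unit), and
#'   `trajectory` when requested. The configuration is attached as attribute
#'   `"config"`.
#' @examples
#' simulate_packaging(sim_config(p_pause_slip = 0), n_traj = 2, seed = 1)
#' @export
simulate_packaging <- function(config, n_traj = 1, seed = NULL,
                               keep_trajectory = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  n_traj <- check_count(n_traj, "n_traj")
  local_seed_if(seed)
  runs <- purrr::map(seq_len(n_traj), function(i) {
    r <- run_one_trajectory(config, keep_trajectory)
    tibble(
      traj_id = i, outcome = r$outcome, pre_packaged_bp = r$pre_packaged,
      unpackaged_final_bp = r$unpackaged_final,
      completion_time = r$completion_time, n_events = r$n_events,
      n_slip_events = r$n_slip_events, mean_velocity = r$mean_velocity,
      trajectory = if (keep_trajectory) list(r$trajectory) else list(NULL)
    )
  })
  out <- dplyr::bind_rows(runs)
  if (!keep_trajectory) out$trajectory <- NULL
  attr(out, "config") <- config
  out
}

#' Summarize simulated packaging conditions
#'
#' Per-condition success fractions and mean velocities of successful
#' trajectories (velocity of a successful run = base pairs packaged divided
#' by completion time, in bp per arbitrary time unit).
#'
#' @param results Tibble of [simulate_packaging()] rows with an added
#'   `condition` column (any label, e.g. the number of inactive subunits).
#' @return Tibble per condition: `n_traj`, `n_success`, `success_fraction`,
#'   `mean_velocity_success` (NA, with a flag, for conditions without
#'   successes), `sd_velocity_success`, `n_censored`.
#' @export
summarize_simulations <- function(results) {
  if (is.null(results) || nrow(results) == 0) abort("`results` must be non-empty.")
  if (is.null(results$condition)) abort("`results` needs a `condition` column.")
  results |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_traj = dplyr::n(),
      n_success = sum(.data$outcome == "success"),
      success_fraction = mean(.data$outcome == "success"),
      mean_velocity_success = ifelse(
        sum(.data$outcome == "success") > 0,
        mean(.data$mean_velocity[.data$outcome == "success"]), NA_real_),
      sd_velocity_success = ifelse(
        sum(.data$outcome == "success") > 1,
        stats::sd(.data$mean_velocity[.data$outcome == "success"]), NA_real_),
      n_censored = sum(.data$outcome == "censored"),
      no_success_flag = sum(.data$outcome == "success") == 0,
      .groups = "drop"
    )
}

#' Keep simulating until a target number of successes
#'
#' Convenience wrapper used for velocity-ratio estimates: runs batches of
#' trajectories until at least `n_success` successful runs are collected
#' (or `max_traj` trajectories have been simulated).
#'
#' @param config A [sim_config()] object.
#' @param n_success Target number of successful trajectories.
#' @param batch Batch size per round.
#' @param max_traj Hard cap on total trajectories.
#' @param seed Optional RNG seed.
#' @return As [simulate_packaging()], pooled over batches.
#' @export
simulate_until_successes <- function(config, n_success, batch = 200L,
                                     max_traj = 1e5, seed = NULL) {
  local_seed_if(seed)
  out <- list()
  got <- 0L; total <- 0L
  while (got < n_success && total < max_traj) {
    res <- simulate_packaging(config, n_traj = batch)
    out[[length(out) + 1L]] <- res
    got <- got + sum(res$outcome == "success")
    total <- total + batch
  }
  res <- dplyr::bind_rows(out)
  res$traj_id <- seq_len(nrow(res))
  attr(res, "config") <- config
  res
}

#' Compare flexible-bypass and strict-arrest coordination schemes
#'
#' Runs the same configuration under the flexible rule (inactive subunits
#' are slipped past) and under strict coordination (the motor arrests
#' permanently when the grip pointer reaches an inactive subunit), and
#' summarizes both. With any inactive subunit, the strict scheme's success
#' fraction is zero by construction.
#'
#' @param config A [sim_config()] object (its `scheme` field is overridden).
#' @param n_traj Trajectories per scheme.
#' @param seed Optional RNG seed (each scheme runs from the same seed).
#' @return Summary tibble as [summarize_simulations()], one row per scheme.
#' @export
coordination_scheme_compare <- function(config, n_traj = 100, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) seed <- as.integer(seed)
  purrr::map_dfr(c("flexible_bypass", "strict_arrest"), function(sch) {
    cfg <- config
    cfg$scheme <- sch
    res <- simulate_packaging(cfg, n_traj = n_traj, seed = seed)
    res$condition <- sch
    summarize_simulations(res)
  })
}
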