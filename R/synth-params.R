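# Parameter constructors for the synthetic single-molecule data generators.
# Each constructor validates the invariants its consumers rely on, so bad
# configurations fail at construction rather than mid-simulation.

#' DNA-engagement kinetics parameters
#'
#' Gap times between successive DNA engagements follow a two-component
#' exponential mixture: short gaps (`tau_short`) within engagement bursts of
#' the motor's DNA-engaging state, and long gaps (`tau_long`) set by the
#' quiescent state. Engagement lifetimes follow a three-component exponential
#' mixture (transient / semi-transient / long-lived); each engagement's
#' observed end is censored by Cy5 photobleaching with exponential lifetime
#' `bleach_lifetime`.
#'
#' Defaults reproduce wild-type motors: gap mixture (0.8, 5 s; 0.2, 40 s)
#' whose amplitude-weighted mean is 12 s, a ~40 s dye photobleaching
#' lifetime, and lifetime classes in which roughly 80% of engagements fail
#' before complete encapsidation.
#'
#' @param amp_short,amp_long Mixture weights of the gap-time components
#'   (must sum to 1).
#' @param tau_short,tau_long Gap-time component means, seconds
#'   (`tau_long > tau_short`).
#' @param lifetime_weights,lifetime_taus Weights (sum 1) and means (s) of the
#'   three-component engagement-lifetime mixture, shortest first.
#' @param bleach_lifetime Mean dye photobleaching lifetime, seconds.
#' @return A list of class `engagement_kinetics`.
#' @export
engagement_kinetics <- function(amp_short = 0.8, tau_short = 5,
                                amp_long = 0.2, tau_long = 40,
                                lifetime_weights = c(0.6, 0.2, 0.2),
                                lifetime_taus = c(0.7, 4, 30),
                                bleach_lifetime = 40) {
  w2 <- c(amp_short, amp_long)
  check_positive(c(tau_short, tau_long, lifetime_taus, bleach_lifetime), "taus")
  if (any(w2 < 0) || abs(sum(w2) - 1) > 1e-9) {
    abort("`amp_short` and `amp_long` must be non-negative and sum to 1.")
  }
  if (length(lifetime_weights) != 3L || length(lifetime_taus) != 3L) {
    abort("Lifetime mixture must have exactly 3 components.")
  }
  if (any(lifetime_weights < 0) || abs(sum(lifetime_weights) - 1) > 1e-9) {
    abort("`lifetime_weights` must be non-negative and sum to 1.")
  }
  if (tau_long <= tau_short) abort("`tau_long` must exceed `tau_short`.")
  structure(
    list(
      amp_short = amp_short, tau_short = tau_short,
      amp_long = amp_long, tau_long = tau_long,
      lifetime_weights = lifetime_weights, lifetime_taus = lifetime_taus,
      bleach_lifetime = bleach_lifetime
    ),
    class = "engagement_kinetics"
  )
}

#' Worm-like-chain elasticity parameters
#'
#' Defaults are standard double-stranded DNA values at room temperature
#' (23 C): persistence length 50 nm, stretch modulus 1000 pN, helix rise
#' 0.34 nm/bp, thermal energy 4.11 pN nm. The default contour length of
#' 1156 nm corresponds to a 3400-bp tether.
#'
#' @param persistence_length nm.
#' @param stretch_modulus pN.
#' @param rise_per_bp nm per base pair.
#' @param contour_length nm.
#' @param thermal_energy pN nm (kT).
#' @return A list of class `wlc_params`.
#' @export
wlc_params <- function(persistence_length = 50, stretch_modulus = 1000,
                       rise_per_bp = 0.34, contour_length = 3400 * 0.34,
                       thermal_energy = 4.11) {
  vals <- c(persistence_length, stretch_modulus, rise_per_bp, contour_length,
            thermal_energy)
  check_positive(vals, "wlc parameters")
  structure(
    list(
      persistence_length = persistence_length,
      stretch_modulus = stretch_modulus,
      rise_per_bp = rise_per_bp,
      contour_length = contour_length,
      thermal_energy = thermal_energy
    ),
    class = "wlc_params"
  )
}

#' Optical-trap extension-trace generator parameters
#'
#' Defaults match wild-type packaging under 5 pN constant force: pause-free
#' velocity 960 bp/s, 1.2 pauses per kb packaged, 0.8 s mean pause duration,
#' a 3400-bp tether, and 2 nm extension noise. A fraction of pauses are
#' "unpackaging" events in which DNA is gradually released at
#' `unpackaging_velocity` (negative, bp/s; observed events range from about
#' -100 to -500 bp/s).
#'
#' @param pause_free_velocity bp/s, > 0.
#' @param pause_rate pauses per kb packaged (homogeneous in packaged length).
#' @param pause_duration_mean seconds.
#' @param unpackaging_fraction probability a pause is an unpackaging event.
#' @param unpackaging_velocity bp/s, `<= 0`.
#' @param noise_sd nm, additive Gaussian per frame.
#' @param force pN, constant load.
#' @param dna_length bp.
#' @param frame_interval seconds (trap sampling; finer than the 0.1 s
#'   velocity-analysis window).
#' @param start_delay_s seconds of pre-packaging plateau at full extension
#'   (models the start time between ATP exposure and the first packaging).
#' @return A list of class `trap_sim_params`.
#' @export
trap_sim_params <- function(pause_free_velocity = 960, pause_rate = 1.2,
                            pause_duration_mean = 0.8,
                            unpackaging_fraction = 0.1,
                            unpackaging_velocity = -300, noise_sd = 2,
                            force = 5, dna_length = 3400,
                            frame_interval = 0.005, start_delay_s = 0) {
  check_positive(pause_free_velocity, "pause_free_velocity")
  check_positive(pause_rate, "pause_rate", strict = FALSE)
  check_positive(pause_duration_mean, "pause_duration_mean")
  check_probability(unpackaging_fraction, "unpackaging_fraction")
  if (unpackaging_velocity > 0) abort("`unpackaging_velocity` must be <= 0.")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  check_positive(force, "force")
  check_positive(dna_length, "dna_length")
  check_positive(frame_interval, "frame_interval")
  check_positive(start_delay_s, "start_delay_s", strict = FALSE)
  structure(
    list(
      pause_free_velocity = pause_free_velocity, pause_rate = pause_rate,
      pause_duration_mean = pause_duration_mean,
      unpackaging_fraction = unpackaging_fraction,
      unpackaging_velocity = unpackaging_velocity, noise_sd = noise_sd,
      force = force, dna_length = dna_length,
      frame_interval = frame_interval, start_delay_s = start_delay_s
    ),
    class = "trap_sim_params"
  )
}
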