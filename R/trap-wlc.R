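# Extensible worm-like-chain elasticity: converting DNA extension under
# constant force to unpackaged base pairs, and screening tethers against the
# model.

#' Relative extension of DNA under force (extensible worm-like chain)
#'
#' High-force interpolation with an enthalpic stretching term:
#' `x / L0 = 1 - (1/2) * sqrt(kT / (F * Lp)) + F / K`.
#' Monotone increasing in force; at 5 pN with standard DNA parameters the
#' value is 0.9409.
#'
#' @param force Force, pN (> 0); vectorized.
#' @param params A [wlc_params()] object.
#' @return Dimensionless fraction of contour length.
#' @export
wlc_relative_extension <- function(force, params = wlc_params()) {
  stopifnot(inherits(params, "wlc_params"))
  if (!is.numeric(force) || any(force <= 0)) abort("`force` must be > 0.")
  1 - 0.5 * sqrt(params$thermal_energy / (force * params$persistence_length)) +
    force / params$stretch_modulus
}

#' Convert between unpackaged base pairs and extension
#'
#' At constant force the tether extension is proportional to the number of
#' unpackaged base pairs: `extension = bp * rise_per_bp * x_rel(F)`. The two
#' functions are exact inverses of each other.
#'
#' @param bp Unpackaged base pairs.
#' @param extension Extension, nm (`>= 0`).
#' @param force Force, pN.
#' @param params A [wlc_params()] object.
#' @return `extension_from_bp()`: nm; `bp_from_extension()`: base pairs.
#' @export
extension_from_bp <- function(bp, force, params = wlc_params()) {
  bp * params$rise_per_bp * wlc_relative_extension(force, params)
}

#' @rdname extension_from_bp
#' @export
bp_from_extension <- function(extension, force, params = wlc_params()) {
  if (any(extension < 0)) abort("`extension` must be >= 0.")
  extension / (params$rise_per_bp * wlc_relative_extension(force, params))
}

#' Screen a tether's force-extension curve against the WLC model
#'
#' Compares a measured force-extension curve to the extensible worm-like
#' chain at the expected contour length, allowing a constant extension
#' offset (bead-size and geometry uncertainty). The offset is fitted by
#' least squares; the tether is rejected if the offset falls outside
#' `offset_window` (default -100 nm to +50 nm) or if the extremum or
#' variance of the offset-corrected residuals exceeds the global thresholds.
#'
#' @param fe_curve Tibble with `force_pN` (monotone) and `extension_nm`.
#' @param params A [wlc_params()] object (its `contour_length` sets the
#'   expected tether length).
#' @param offset_window Acceptable extension offset, nm, `c(lo, hi)`.
#' @param max_residual Residual extremum threshold, nm.
#' @param max_residual_var Residual variance threshold, nm^2.
#' @return One-row tibble: `accepted`, `offset_nm`, `resid_extremum_nm`,
#'   `resid_var_nm2`, `reason` (`"ok"` or the first failed check).
#' @export
screen_tether <- function(fe_curve, params = wlc_params(),
                          offset_window = c(-100, 50),
                          max_residual = 15, max_residual_var = 25) {
  f <- fe_curve$force_pN
  ext <- fe_curve$extension_nm
  if (is.null(f) || is.null(ext)) abort("`fe_curve` needs `force_pN` and `extension_nm`.")
  if (!(all(diff(f) > 0) || all(diff(f) < 0))) {
    abort("Force grid must be monotone.")
  }
  if (diff(range(f)) < 2) abort("Force-extension curve must span >= 2 pN.")
  model <- params$contour_length * wlc_relative_extension(f, params)
  offset <- mean(ext - model)
  resid <- ext - model - offset
  extremum <- max(abs(resid))
  v <- stats::var(resid)
  reason <- if (offset < offset_window[1] || offset > offset_window[2]) {
    "offset_outside_window"
  } else if (extremum > max_residual) {
    "residual_extremum"
  } else if (v > max_residual_var) {
    "residual_variance"
  } else {
    "ok"
  }
  tibble(
    accepted = reason == "ok", offset_nm = offset,
    resid_extremum_nm = extremum, resid_var_nm2 = v, reason = reason
  )
}
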