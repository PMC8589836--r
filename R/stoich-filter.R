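# Edge-preserving nonlinear forward-backward filter for stepwise
# photobleaching trajectories.

#' Filter parameters for the nonlinear forward-backward filter
#'
#' @param window_count Base predictor window, frames (default 4).
#' @param bank_size Number of predictors per direction (default 3); the j-th
#'   predictor in a bank averages over `window_count * j` frames.
#' @param weight_exponent Exponent applied to the inverse prediction-error
#'   weights (default 20). Large values make the weighting nearly
#'   winner-take-all, which is what preserves step edges.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(window_count = 4, bank_size = 3,
                          weight_exponent = 20) {
  window_count <- check_count(window_count, "window_count")
  bank_size <- check_count(bank_size, "bank_size")
  weight_exponent <- check_count(weight_exponent, "weight_exponent")
  if (window_count < 1 || bank_size < 1 || weight_exponent < 1) {
    abort("All filter parameters must be positive integers.")
  }
  structure(
    list(window_count = window_count, bank_size = bank_size,
         weight_exponent = weight_exponent),
    class = "filter_params"
  )
}

# causal running mean of the previous `w` values (not including the current
# one); x must already be edge-padded by the caller
causal_mean <- function(x, w) {
  cs <- cumsum(x)
  n <- length(x)
  out <- rep(NA_real_, n)
  idx <- (w + 1):n
  out[idx] <- (cs[idx - 1] - c(0, cs)[idx - w]) / w
  out
}

# trailing running mean over [t - w + 1, t], including the current value
trailing_mean <- function(x, w) {
  cs <- cumsum(x)
  n <- length(x)
  out <- rep(NA_real_, n)
  idx <- w:n
  out[idx] <- (cs[idx] - c(0, cs)[idx - w + 1]) / w
  out
}

#' Nonlinear forward-backward filter
#'
#' Edge-preserving smoother for stepwise fluorescence trajectories. Two banks
#' of running-mean predictors are maintained at each frame: forward
#' predictors averaging the previous `window_count * j` frames and backward
#' predictors averaging the following `window_count * j` frames
#' (`j = 1..bank_size`). Each predictor is weighted by its mean squared
#' one-step prediction error over its own window, raised to the power
#' `-weight_exponent`; the output is the weighted mean of all predictors.
#' Near a step, predictors whose window straddles the edge incur large
#' prediction errors and are suppressed, so edges are preserved while flat
#' regions are averaged.
#'
#' The trace is edge-padded by replicating its first and last values over the
#' largest predictor window, so a constant trace is returned unchanged.
#'
#' @param trace Tibble with columns `time_s` and `intensity_au` (one trace).
#' @param params A [filter_params()] object; the defaults
#'   (window 4, bank 3, exponent 20) are the values used throughout the
#'   fluorescence analysis.
#' @return The trace tibble with `intensity_au` replaced by the filtered
#'   signal (same length and time grid).
#' @export
nonlinear_fb_filter <- function(trace, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  x <- trace$intensity_au
  if (is.null(x)) abort("`trace` must have an `intensity_au` column.")
  if (anyNA(x) || any(!is.finite(x))) abort("Intensities must be finite.")
  span <- params$window_count * params$bank_size
  if (length(x) <= 2L * span) {
    abort(sprintf("Trace too short: need > %d frames for the filter span.", 2L * span))
  }
  n <- length(x)
  pad <- span
  xp <- c(rep(x[1], pad), x, rep(x[n], pad))
  np <- length(xp)
  windows <- params$window_count * seq_len(params$bank_size)

  preds <- matrix(NA_real_, np, 2L * length(windows))
  errs <- matrix(NA_real_, np, 2L * length(windows))
  for (j in seq_along(windows)) {
    w <- windows[j]
    fwd <- causal_mean(xp, w)
    bwd <- rev(causal_mean(rev(xp), w))
    preds[, j] <- fwd
    preds[, j + length(windows)] <- bwd
    # mean squared one-step prediction error over each predictor's window:
    # past window for the forward predictor, future window for the backward
    e2f <- (xp - fwd)^2
    e2b <- (xp - bwd)^2
    e2f[is.na(e2f)] <- 0
    e2b[is.na(e2b)] <- 0
    # error averages include the current frame, so a predictor whose window
    # straddles a step is suppressed at the very first frame past the edge
    errs[, j] <- trailing_mean(e2f, w)
    errs[, j + length(windows)] <- rev(trailing_mean(rev(e2b), w))
  }

  core <- (pad + 1):(pad + n)
  preds <- preds[core, , drop = FALSE]
  errs <- errs[core, , drop = FALSE]
  errs[is.na(errs)] <- Inf
  preds[is.na(preds)] <- 0

  min_e <- pmax(apply(errs, 1L, min), 0)
  # normalize by the row minimum before exponentiating to avoid overflow at
  # large exponents; zero-error predictors (noiseless data) get weight 1
  ratio <- errs / ifelse(min_e > 0, min_e, 1) # row-wise: column length == n
  wts <- ratio^(-params$weight_exponent)
  zero_rows <- min_e == 0
  if (any(zero_rows)) {
    wts[zero_rows, ] <- (errs[zero_rows, , drop = FALSE] == 0) * 1
  }
  wts[!is.finite(wts)] <- 0
  wsum <- rowSums(wts)
  flat <- wsum == 0
  y <- rowSums(wts * preds) / ifelse(flat, 1, wsum)
  y[flat] <- x[flat]

  out <- trace
  out$intensity_au <- y
  out
}
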