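# Hetero-pentamer composition statistics and coordination activity models.
#
# A motor assembled from a pool containing a molar fraction `p` of
# ATPase-inactive subunits is a random pentamer: the number of *active*
# subunits k is Binomial(n, 1 - p). Ensemble packaging activity is modelled
# by assuming a minimum number of active subunits (k_min) is required for any
# activity and that each active subunit contributes 1/n of full activity.

#' Composition distribution of inactive-subunit-doped motors
#'
#' Probability that a ring motor assembled from a doped subunit pool contains
#' `k` active subunits, for each `k = 0..n`. Subunits are drawn independently;
#' active and inactive monomers are assumed to assemble with equal affinity,
#' so the count of active subunits is `Binomial(n, 1 - doping_p)`.
#'
#' @param doping_p Per-subunit probability of being inactive (the molar
#'   fraction of inactive monomers in the assembly pool). May be a vector.
#' @param n_subunits Ring size (default 5, the T4 gp17 pentamer).
#'
#' @return A tibble with columns `doping_p`, `k_active`, `probability`.
#'   Probabilities sum to 1 over `k_active` for each `doping_p`.
#' @examples
#' composition_pmf(0.5)
#' @export
composition_pmf <- function(doping_p, n_subunits = 5) {
  check_probability(doping_p, "doping_p")
  n <- check_count(n_subunits, "n_subunits")
  tidyr::expand_grid(doping_p = doping_p, k_active = 0:n) |>
    dplyr::mutate(
      probability = stats::dbinom(.data$k_active, n, 1 - .data$doping_p)
    )
}

#' Doping fraction from molar amounts
#'
#' Converts molar amounts of inactive and active (wild-type) subunits into the
#' per-subunit inactive probability used by [composition_pmf()]: the molar
#' ratio of inactive subunits to all subunits.
#'
#' @param inactive_amount,active_amount Molar quantities (any common unit),
#'   each `>= 0` and not both zero.
#' @return The doping fraction `inactive / (inactive + active)`.
#' @examples
#' doping_fraction(1, 1) # a 1:1 mix -> 0.5
#' @export
doping_fraction <- function(inactive_amount, active_amount) {
  check_positive(inactive_amount, "inactive_amount", strict = FALSE)
  check_positive(active_amount, "active_amount", strict = FALSE)
  tot <- inactive_amount + active_amount
  if (any(tot == 0)) abort("`inactive_amount` and `active_amount` must not both be zero.")
  inactive_amount / tot
}

#' Predicted ensemble packaging activity under a coordination model
#'
#' Normalized ensemble activity of a population of randomly assembled motors
#' when at least `k_min` active subunits are required for packaging and each
#' active subunit contributes a fraction `1/n` of full activity:
#' `Activity(k_min, p) = (1/n) * sum_{k = k_min}^{n} k * f(k, p)`,
#' with `f(k, p)` the composition pmf. `k_min = 1` is a completely
#' uncoordinated motor (activity `1 - p`); `k_min = n` is strict coordination
#' (activity `(1 - p)^n`).
#'
#' @param k_min Minimum number of active subunits required for activity,
#'   in `1..n_subunits`.
#' @param doping_p Per-subunit inactive probability; vectorized.
#' @inheritParams composition_pmf
#' @return Numeric vector of activities in `[0, 1]`, recycled over
#'   `doping_p`.
#' @seealso [activity_curves()], [fit_kmin()]
#' @export
predicted_activity <- function(k_min, doping_p, n_subunits = 5) {
  n <- check_count(n_subunits, "n_subunits")
  k_min <- check_count(k_min, "k_min")
  if (any(k_min < 1L) || any(k_min > n)) {
    abort("`k_min` must lie in [1, n_subunits].")
  }
  check_probability(doping_p, "doping_p")
  both <- vctrs_recycle(k_min, doping_p)
  mapply(function(km, p) {
    k <- km:n
    sum(k * stats::dbinom(k, n, 1 - p)) / n
  }, both[[1]], both[[2]])
}

# minimal common-length recycling (length-1 or equal lengths)
vctrs_recycle <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la == lb) return(list(a, b))
  if (la == 1L) return(list(rep(a, lb), b))
  if (lb == 1L) return(list(a, rep(b, la)))
  abort("Arguments must have length 1 or a common length.")
}

#' Activity-vs-doping curves for all coordination levels
#'
#' @param doping_grid Grid of doping fractions.
#' @param k_min Coordination levels to tabulate (default all of `1..n`).
#' @inheritParams composition_pmf
#' @return Tibble with columns `k_min`, `doping_p`, `activity`.
#' @export
activity_curves <- function(doping_grid = seq(0, 1, by = 0.01),
                            k_min = NULL, n_subunits = 5) {
  n <- check_count(n_subunits, "n_subunits")
  if (is.null(k_min)) k_min <- seq_len(n)
  tidyr::expand_grid(k_min = as.integer(k_min), doping_p = doping_grid) |>
    dplyr::mutate(
      activity = predicted_activity(.data$k_min, .data$doping_p, n)
    )
}

#' Fit the coordination level to activity-vs-doping observations
#'
#' Selects the coordination level `k_min` whose predicted activity curve best
#' matches observed (doping fraction, normalized activity) pairs by least
#' squares. Observed activities are assumed pre-normalized to the undoped
#' condition (activity at `doping_p = 0` equal to 1), matching how gel-based
#' packaging activities are normalized to the all-wild-type lane.
#'
#' @param data Data frame with one row per observation.
#' @param doping_col,activity_col Column names (strings) holding the doping
#'   fraction and the normalized activity.
#' @inheritParams composition_pmf
#' @return An object of class `kmin_fit` with [tidy()] (per-`k_min` residual
#'   sum of squares) and [glance()] methods. Ties in RSS are broken toward
#'   the larger (more coordinated) `k_min`.
#' @examples
#' obs <- activity_curves(seq(0, 0.8, 0.2), k_min = 3) |>
#'   dplyr::rename(activity_obs = activity)
#' fit_kmin(obs, activity_col = "activity_obs")
#' @export
fit_kmin <- function(data, doping_col = "doping_p", activity_col = "activity",
                     n_subunits = 5) {
  n <- check_count(n_subunits, "n_subunits")
  p <- data[[doping_col]]
  a <- data[[activity_col]]
  if (is.null(p) || is.null(a)) abort("`data` must contain the doping and activity columns.")
  if (length(p) < 2L || length(unique(p)) < 2L) {
    abort("Degenerate design: need observations at >= 2 distinct doping fractions.")
  }
  check_probability(p, doping_col)
  rss <- vapply(seq_len(n), function(km) {
    sum((a - predicted_activity(km, p, n))^2)
  }, numeric(1))
  # ties toward larger k_min (more coordinated)
  best <- max(which(rss <= min(rss) + 1e-15))
  structure(
    list(
      k_min = best,
      rss = tibble(k_min = seq_len(n), rss = rss),
      n_subunits = n,
      n_obs = length(p),
      data = tibble(doping_p = p, activity = a)
    ),
    class = c("kmin_fit", "motorlab_fit")
  )
}

#' @export
tidy.kmin_fit <- function(x, ...) x$rss

#' @export
glance.kmin_fit <- function(x, ...) {
  tibble(
    k_min = x$k_min,
    rss = x$rss$rss[x$k_min],
    n_obs = x$n_obs,
    n_subunits = x$n_subunits
  )
}

#' @export
autoplot.kmin_fit <- function(object, ...) {
  curves <- activity_curves(n_subunits = object$n_subunits)
  ggplot2::ggplot(curves, ggplot2::aes(.data$doping_p, .data$activity)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$k_min,
                                    colour = factor(.data$k_min))) +
    ggplot2::geom_point(data = object$data, colour = "black") +
    ggplot2::labs(
      x = "doping fraction (inactive subunits)",
      y = "normalized packaging activity",
      colour = expression(k[min]),
      title = sprintf("Best coordination level: k_min = %d", object$k_min)
    )
}
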