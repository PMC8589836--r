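# Maximum-likelihood exponential mixtures with right censoring.
#
# Gap times between DNA engagements follow a two-exponential mixture
# (engagement-burst vs quiescent-state gaps); engagement lifetimes follow a
# three-exponential mixture (transient / semi-transient / long-lived).
# Durations cut short by the end of a recording enter the likelihood through
# the survival function. Fitting is by EM: the E-step computes component
# responsibilities (density for observed durations, survival for censored
# ones); the M-step is the censored-exponential MLE within each component,
# time at risk over expected event count.

em_exp_mixture <- function(t, delta, tau0, w0, max_iter = 1000L, tol = 1e-9) {
  k <- length(tau0)
  tau <- tau0; w <- w0
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # E-step in logs for numerical stability
    lp <- vapply(seq_len(k), function(j) {
      log(w[j]) + ifelse(delta, -log(tau[j]) - t / tau[j], -t / tau[j])
    }, numeric(length(t)))
    lp <- matrix(lp, ncol = k)
    m <- apply(lp, 1L, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    r <- exp(lp - lse)
    # M-step
    w <- colMeans(r)
    ev <- colSums(r * delta)
    tau_new <- colSums(r * t) / pmax(ev, 1e-12)
    tau <- pmax(tau_new, 1e-12)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  ord <- order(tau)
  list(weights = w[ord], taus = tau[ord], log_lik = ll, iterations = it)
}

#' Fit a censored exponential mixture to dwell times
#'
#' Maximum-likelihood mixture-of-exponentials fit with right censoring,
#' with the number of components selected among `candidate_orders` by BIC.
#' Each candidate order is fitted from several spread-out starting points to
#' guard against local optima. The amplitude-weighted mean lifetime
#' `tau_avg = sum(w_i * tau_i)` is reported alongside the components.
#'
#' @param durations Dwell times, seconds, `> 0`.
#' @param censored Logical vector: `TRUE` where the duration is a lower
#'   bound (right-censored, e.g. cut off by the end of the recording).
#'   Default: none censored.
#' @param candidate_orders Model orders to compare (default `1:3`).
#' @param n_restarts EM restarts per order.
#' @return An object of class `exp_mixture_fit`: `n_components`, `weights`,
#'   `taus` (ascending), `tau_avg`, `log_lik`, and `selection` (per-order
#'   BIC table). [tidy()] returns the components, [glance()] the headline
#'   fit.
#' @examples
#' set.seed(1)
#' x <- c(rexp(300, 1 / 5), rexp(100, 1 / 40))
#' fit_exponential_mixture(x, candidate_orders = 1:2)
#' @export
fit_exponential_mixture <- function(durations, censored = NULL,
                                    candidate_orders = 1:3,
                                    n_restarts = 5L) {
  if (!is.numeric(durations) || length(durations) == 0 || any(durations <= 0)) {
    abort("`durations` must be positive numbers.")
  }
  if (is.null(censored)) censored <- rep(FALSE, length(durations))
  if (length(censored) != length(durations)) {
    abort("`censored` must match `durations` in length.")
  }
  candidate_orders <- check_count(candidate_orders, "candidate_orders")
  n <- length(durations)
  if (n < 50L) warn("Fewer than 50 durations: mixture fit may be unstable.")
  delta <- !censored
  if (sum(delta) == 0L) abort("All durations are censored; nothing to fit.")
  n_distinct <- length(unique(durations[delta]))
  feasible <- candidate_orders[candidate_orders <= n_distinct & candidate_orders >= 1L]
  if (length(feasible) == 0L) {
    abort("Degenerate fit: fewer distinct observed durations than mixture components.")
  }

  mu <- sum(durations) / sum(delta)
  fits <- purrr::map(feasible, function(k) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      # geometric spread of starting lifetimes around the censored-MLE mean,
      # jittered across restarts
      spread <- exp(seq(-1.5, 1.5, length.out = k)) * mu
      if (r > 1L) spread <- spread * exp(stats::runif(k, -1, 1))
      fit <- em_exp_mixture(durations, delta, tau0 = spread,
                            w0 = rep(1 / k, k))
      if (is.null(best) || fit$log_lik > best$log_lik) best <- fit
    }
    best$order <- k
    best$bic <- -2 * best$log_lik + (2 * k - 1) * log(n)
    best
  })

  sel <- tibble(
    order = vapply(fits, `[[`, integer(1), "order"),
    log_lik = vapply(fits, `[[`, numeric(1), "log_lik"),
    bic = vapply(fits, `[[`, numeric(1), "bic")
  )
  best <- fits[[which.min(sel$bic)]]

  structure(
    list(
      n_components = best$order,
      weights = best$weights,
      taus = best$taus,
      tau_avg = sum(best$weights * best$taus),
      log_lik = best$log_lik,
      selection = sel,
      n_obs = n,
      n_censored = sum(censored)
    ),
    class = c("exp_mixture_fit", "motorlab_fit")
  )
}

#' @export
tidy.exp_mixture_fit <- function(x, ...) {
  tibble(component = seq_len(x$n_components), weight = x$weights,
         tau_s = x$taus)
}

#' @export
glance.exp_mixture_fit <- function(x, ...) {
  tibble(n_components = x$n_components, tau_avg_s = x$tau_avg,
         log_lik = x$log_lik, n_obs = x$n_obs, n_censored = x$n_censored)
}

#' @export
autoplot.exp_mixture_fit <- function(object, ...) {
  tmax <- max(object$taus) * 4
  grid <- tibble(t = seq(0, tmax, length.out = 400))
  grid$survival <- vapply(grid$t, function(tt) {
    sum(object$weights * exp(-tt / object$taus))
  }, numeric(1))
  ggplot2::ggplot(grid, ggplot2::aes(.data$t, .data$survival)) +
    ggplot2::geom_line(colour = "blue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dwell time (s)", y = "survival probability",
                  title = sprintf("%d-exponential fit, tau_avg = %.1f s",
                                  object$n_components, object$tau_avg))
}
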