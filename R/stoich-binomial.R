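# Binomial stoichiometry inference from pooled photobleaching step counts.
#
# The probability of detecting k labeled subunits in a motor of stoichiometry
# n with labeling efficiency p is Binomial(n, p). Because a motor with zero
# labels produces no fluorescent spot, the observable distribution is the
# zero-truncated binomial; both likelihoods are available.

#' Step-count probability mass function
#'
#' Binomial pmf for the number of detected labeled subunits, optionally
#' zero-truncated (a motor with zero labels is invisible, so the observable
#' counts are conditioned on `k >= 1`).
#'
#' @param n_subunits Stoichiometry `n`.
#' @param label_prob Labeling efficiency `p`.
#' @param truncate_zero Condition on at least one label.
#' @return Tibble with columns `k` and `probability`.
#' @export
step_count_pmf <- function(n_subunits, label_prob, truncate_zero = FALSE) {
  n <- check_count(n_subunits, "n_subunits")
  check_probability(label_prob, "label_prob")
  k <- if (truncate_zero) seq_len(n) else 0:n
  pr <- stats::dbinom(k, n, label_prob)
  if (truncate_zero) pr <- pr / (1 - (1 - label_prob)^n)
  tibble(k = k, probability = pr)
}

trunc_binom_loglik <- function(p, counts, n) {
  sum(stats::dbinom(counts, n, p, log = TRUE)) -
    length(counts) * log1p(-(1 - p)^n)
}

#' Fit the binomial stoichiometry model to pooled step counts
#'
#' For each candidate stoichiometry `n`, finds the maximum-likelihood
#' labeling efficiency `p` under the (optionally zero-truncated) binomial
#' model, and selects the candidate with the highest likelihood. A candidate
#' is infeasible (zero likelihood) if any observed count exceeds it.
#'
#' Without zero-truncation the MLE is the closed form `mean(counts) / n`;
#' with truncation it is found by one-dimensional optimization.
#'
#' @param counts Integer vector of per-trace photobleaching step counts.
#' @param candidate_n Candidate stoichiometries (default 3 to 8).
#' @param truncate_zero Use the zero-truncated likelihood (default `TRUE`;
#'   motors with zero labels produce no spot). When set, all counts must be
#'   `>= 1`.
#' @return An object of class `binom_stoich_fit` with `n_hat`, `p_hat` and a
#'   per-candidate table (feasibility, `p_hat`, log-likelihood, chi-squared
#'   goodness-of-fit). Ties in likelihood break toward the smaller `n`.
#'   [tidy()] returns the per-candidate table; [glance()] the headline fit.
#' @examples
#' counts <- c(2, 3, 4, 5, 3, 2, 4)
#' fit_binomial_stoichiometry(counts, candidate_n = 4:6)
#' @export
fit_binomial_stoichiometry <- function(counts, candidate_n = 3:8,
                                       truncate_zero = TRUE) {
  counts <- check_count(counts, "counts")
  if (length(counts) == 0) abort("`counts` must be non-empty.")
  candidate_n <- check_count(candidate_n, "candidate_n")
  if (truncate_zero && any(counts == 0)) {
    abort("Zero counts are unobservable under the zero-truncated model; use `truncate_zero = FALSE` or drop them.")
  }
  ncounts <- length(counts)

  rows <- purrr::map(candidate_n, function(n) {
    if (max(counts) > n) {
      return(tibble(n = n, feasible = FALSE, p_hat = NA_real_,
                    log_lik = -Inf, chisq = NA_real_, df = NA_integer_))
    }
    if (truncate_zero) {
      opt <- stats::optimize(trunc_binom_loglik, c(1e-9, 1 - 1e-9),
                             counts = counts, n = n, maximum = TRUE)
      p_hat <- opt$maximum
      ll <- opt$objective
    } else {
      p_hat <- mean(counts) / n
      ll <- sum(stats::dbinom(counts, n, p_hat, log = TRUE))
    }
    pmf <- step_count_pmf(n, p_hat, truncate_zero)
    obs <- tabulate(factor(counts, levels = pmf$k), nbins = nrow(pmf))
    expd <- ncounts * pmf$probability
    ok <- expd > 0
    chisq <- sum((obs[ok] - expd[ok])^2 / expd[ok])
    tibble(n = n, feasible = TRUE, p_hat = p_hat, log_lik = ll,
           chisq = chisq, df = sum(ok) - 2L)
  })
  table <- dplyr::bind_rows(rows)

  if (!any(table$feasible)) {
    abort("No feasible candidate stoichiometry: every candidate is exceeded by an observed count.")
  }
  feas <- dplyr::filter(table, .data$feasible)
  best <- feas[which.max(feas$log_lik), ] # which.max -> first max: smaller n on ties

  structure(
    list(
      n_hat = best$n, p_hat = best$p_hat, log_lik = best$log_lik,
      truncated = truncate_zero, table = table, counts = counts,
      n_obs = ncounts
    ),
    class = c("binom_stoich_fit", "motorlab_fit")
  )
}

#' @export
tidy.binom_stoich_fit <- function(x, ...) x$table

#' @export
glance.binom_stoich_fit <- function(x, ...) {
  tibble(n_hat = x$n_hat, p_hat = x$p_hat, log_lik = x$log_lik,
         truncated = x$truncated, n_obs = x$n_obs)
}

#' @export
autoplot.binom_stoich_fit <- function(object, ...) {
  pmf <- step_count_pmf(object$n_hat, object$p_hat, object$truncated)
  obs <- tibble(k = object$counts) |>
    dplyr::count(.data$k) |>
    dplyr::mutate(frac = .data$n / sum(.data$n))
  ggplot2::ggplot(obs, ggplot2::aes(.data$k, .data$frac)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_line(data = pmf, ggplot2::aes(.data$k, .data$probability),
                       colour = "blue") +
    ggplot2::geom_point(data = pmf, ggplot2::aes(.data$k, .data$probability),
                        colour = "blue") +
    ggplot2::labs(x = "photobleaching steps", y = "fraction of traces",
                  title = sprintf("Binomial fit: n = %d, p = %.2f",
                                  object$n_hat, object$p_hat))
}

#' Per-candidate stoichiometry report
#'
#' Compares candidate stoichiometries on pooled step counts: likelihood and
#' chi-squared statistics per candidate, predicted-vs-observed histograms,
#' and, per candidate, the expected number of traces with counts exceeding
#' it (the statistic that rules out too-small stoichiometries: observed
#' counts above a candidate make it infeasible outright, while a larger
#' candidate predicts counts that are never observed).
#'
#' @inheritParams fit_binomial_stoichiometry
#' @return A list of class `stoich_report`: `fits` (per-candidate table with
#'   `n_traces_over_n` observed), `histograms` (observed and expected
#'   fractions per candidate), `n_obs`, and a `low_n` warning flag for
#'   degenerate inputs (fewer than 10 traces).
#' @export
stoichiometry_report <- function(counts, candidate_n = 3:8,
                                 truncate_zero = TRUE) {
  counts <- check_count(counts, "counts")
  if (length(counts) == 0) abort("`counts` must be non-empty.")
  low_n <- length(counts) < 10L
  if (low_n) {
    warn("Fewer than 10 traces: stoichiometry report will be unstable.")
  }
  fit <- fit_binomial_stoichiometry(counts, candidate_n, truncate_zero)
  fits <- fit$table |>
    dplyr::mutate(n_traces_over_n = vapply(.data$n, function(nn) sum(counts > nn),
                                           integer(1)))
  histograms <- purrr::map(seq_len(nrow(fits)), function(i) {
    nn <- fits$n[i]
    if (!fits$feasible[i]) return(NULL)
    pmf <- step_count_pmf(nn, fits$p_hat[i], truncate_zero)
    obs <- tabulate(factor(counts, levels = pmf$k), nbins = nrow(pmf))
    tibble(n = nn, k = pmf$k, observed = obs / length(counts),
           expected = pmf$probability)
  }) |> dplyr::bind_rows()
  structure(
    list(fits = fits, histograms = histograms, n_obs = length(counts),
         n_hat = fit$n_hat, p_hat = fit$p_hat, low_n = low_n),
    class = "stoich_report"
  )
}
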