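test_that("single-exponential rate is recovered within 5% at n = 1e4", {
  set.seed(1)
  x <- rexp(1e4, 1 / 7)
  fit <- fit_exponential_mixture(x, candidate_orders = 1)
  expect_lt(abs(fit$taus - 7) / 7, 0.05)
  expect_equal(fit$tau_avg, fit$taus)
})

test_that("tau_avg is the amplitude-weighted mean of the fitted lifetimes", {
  set.seed(2)
  x <- c(rexp(1600, 1 / 5), rexp(400, 1 / 40))
  fit <- fit_exponential_mixture(x, candidate_orders = 2)
  expect_equal(fit$tau_avg, sum(fit$weights * fit$taus), tolerance = 1e-12)
  expect_true(all(diff(fit$taus) > 0))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
})

test_that("two-component gap mixture is selected and tau_avg lands near 12 s", {
  set.seed(3)
  n <- 2000
  comp <- runif(n) < 0.2
  x <- ifelse(comp, rexp(n, 1 / 40), rexp(n, 1 / 5))
  fit <- fit_exponential_mixture(x, candidate_orders = 1:2)
  expect_equal(fit$n_components, 2L)
  expect_lt(abs(fit$tau_avg - 12) / 12, 0.1)
  sel <- fit$selection
  expect_lt(sel$bic[sel$order == 2], sel$bic[sel$order == 1])
})

test_that("censored likelihood reduces to the uncensored one without censoring", {
  set.seed(4)
  x <- c(rexp(300, 1 / 5), rexp(100, 1 / 40))
  f1 <- fit_exponential_mixture(x, candidate_orders = 2)
  # manual uncensored mixture log-likelihood at the fitted parameters
  ll <- sum(log(f1$weights[1] / f1$taus[1] * exp(-x / f1$taus[1]) +
                  f1$weights[2] / f1$taus[2] * exp(-x / f1$taus[2])))
  expect_equal(f1$log_lik, ll, tolerance = 1e-9)
})

test_that("censoring is handled in the likelihood, not by dropping values", {
  set.seed(5)
  full <- rexp(4000, 1 / 20)
  cens <- pmin(full, 30)
  flag <- full > 30
  fit <- fit_exponential_mixture(cens, censored = flag, candidate_orders = 1)
  expect_lt(abs(fit$taus - 20) / 20, 0.1)
  # ignoring censoring underestimates the lifetime badly
  naive <- fit_exponential_mixture(cens, candidate_orders = 1)
  expect_lt(naive$taus, fit$taus)
  # cross-check the censored single-exponential MLE against survreg
  if (requireNamespace("survival", quietly = TRUE)) {
    sr <- survival::survreg(survival::Surv(cens, !flag) ~ 1,
                            dist = "exponential")
    expect_equal(fit$taus, exp(unname(coef(sr))), tolerance = 1e-3)
  }
})

test_that("survival-curve least squares and the MLE agree on tau", {
  set.seed(6)
  x <- rexp(1e4, 1 / 9)
  mle <- fit_exponential_mixture(x, candidate_orders = 1)$taus
  # least squares on log empirical survival (independent fitting route)
  xs <- sort(x)
  surv <- 1 - (seq_along(xs) - 0.5) / length(xs)
  keep <- surv > 0.01
  ls_tau <- -1 / coef(lm(log(surv[keep]) ~ xs[keep] - 1))[[1]]
  expect_lt(abs(mle - ls_tau) / ls_tau, 0.1)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_exponential_mixture(numeric(0)), "positive")
  expect_error(fit_exponential_mixture(c(-1, 2)), "positive")
  expect_error(suppressWarnings(
    fit_exponential_mixture(rep(2, 60), candidate_orders = 2)
  ), "[Dd]egenerate")
  expect_warning(fit_exponential_mixture(rexp(10, 1), candidate_orders = 1),
                 "Fewer than 50")
})
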