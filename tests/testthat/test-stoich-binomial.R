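test_that("step-count pmf normalizes for plain and zero-truncated forms", {
  for (p in c(0.05, 0.3, 0.66, 0.95)) {
    expect_equal(sum(step_count_pmf(5, p)$probability), 1, tolerance = 1e-12)
    expect_equal(sum(step_count_pmf(5, p, truncate_zero = TRUE)$probability), 1,
                 tolerance = 1e-12)
    expect_equal(sum(step_count_pmf(8, p, TRUE)$probability), 1, tolerance = 1e-12)
  }
})

test_that("untruncated MLE for p at fixed n is mean(counts)/n exactly", {
  fit <- fit_binomial_stoichiometry(c(2, 3, 4), candidate_n = 5,
                                    truncate_zero = FALSE)
  expect_equal(fit$p_hat, 0.6, tolerance = 1e-12)
  set.seed(1)
  counts <- rbinom(200, 7, 0.4)
  fit7 <- fit_binomial_stoichiometry(counts, candidate_n = 7,
                                     truncate_zero = FALSE)
  expect_equal(fit7$p_hat, mean(counts) / 7, tolerance = 1e-12)
})

test_that("candidates exceeded by an observed count are infeasible", {
  fit <- fit_binomial_stoichiometry(rep(5L, 20), candidate_n = c(4, 5, 6))
  expect_equal(fit$n_hat, 5)
  expect_gt(fit$p_hat, 0.99)
  expect_false(fit$table$feasible[fit$table$n == 4])

  rep6 <- stoichiometry_report(c(2, 3, 6, 4, 2, 3, 4, 5, 3, 2), candidate_n = 3:8)
  expect_false(rep6$fits$feasible[rep6$fits$n == 5])
  expect_equal(rep6$fits$n_traces_over_n[rep6$fits$n == 5], 1L)

  expect_error(fit_binomial_stoichiometry(rep(9L, 5), candidate_n = 3:8),
               "feasible")
  expect_error(fit_binomial_stoichiometry(integer(0)), "non-empty")
  expect_error(fit_binomial_stoichiometry(c(0L, 2L), truncate_zero = TRUE),
               "unobservable")
})

test_that("zero-truncated fit recovers n = 5, p = 0.66 at the study scale", {
  set.seed(2)
  counts <- sample(1:5, 486, replace = TRUE,
                   prob = dbinom(1:5, 5, 0.66) / (1 - dbinom(0, 5, 0.66)))
  fit <- fit_binomial_stoichiometry(counts)
  expect_equal(fit$n_hat, 5)
  expect_lt(abs(fit$p_hat - 0.66), 0.05)
})

test_that("n = 5 beats n = 4 and n = 6 by likelihood in >=95% of replicates", {
  set.seed(3)
  wins <- replicate(100, {
    counts <- sample(1:5, 486, replace = TRUE,
                     prob = dbinom(1:5, 5, 0.66) / (1 - dbinom(0, 5, 0.66)))
    tab <- fit_binomial_stoichiometry(counts, candidate_n = 4:6)$table
    ll <- tab$log_lik
    ll[tab$n == 5] > ll[tab$n == 4] && ll[tab$n == 5] > ll[tab$n == 6]
  })
  expect_gte(mean(wins), 0.95)
})

test_that("median p-hat bias is below 0.02 at 486 traces", {
  set.seed(4)
  p_hats <- replicate(60, {
    counts <- sample(1:5, 486, replace = TRUE,
                     prob = dbinom(1:5, 5, 0.66) / (1 - dbinom(0, 5, 0.66)))
    fit_binomial_stoichiometry(counts, candidate_n = 5)$p_hat
  })
  expect_lt(abs(median(p_hats) - 0.66), 0.02)
})

test_that("degenerate single-trace input is reported with a warning", {
  expect_warning(rep1 <- stoichiometry_report(3L), "unstable")
  expect_true(rep1$low_n)
  expect_s3_class(rep1$fits, "tbl_df")
})
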