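test_that("composition pmf matches the binomial model and normalizes", {
  for (p in seq(0, 1, by = 0.1)) {
    pmf <- composition_pmf(p)
    expect_equal(sum(pmf$probability), 1, tolerance = 1e-12)
  }
  pmf <- composition_pmf(0.5)
  expect_equal(pmf$probability[pmf$k_active == 5], 0.03125, tolerance = 1e-12)
  expect_equal(1 - pmf$probability[pmf$k_active == 5], 0.96875, tolerance = 1e-12)
  expect_equal(sum(pmf$probability[pmf$k_active %in% c(3, 4)]), 0.46875,
               tolerance = 1e-12)
  # degenerate pools
  expect_equal(composition_pmf(0)$probability[6], 1)
  expect_equal(composition_pmf(1)$probability[1], 1)
  expect_error(composition_pmf(1.2), "0, 1")
})

test_that("doping fraction is the molar ratio of inactive to all subunits", {
  expect_equal(doping_fraction(1, 1), 0.5)
  expect_equal(doping_fraction(0, 3), 0)
  expect_equal(doping_fraction(3, 0), 1)
  expect_error(doping_fraction(0, 0), "both")
})

test_that("predicted activity equals brute-force enumeration over 2^5 states", {
  for (km in 1:5) {
    for (p in seq(0, 1, by = 0.1)) {
      expect_equal(predicted_activity(km, p),
                   brute_force_activity(km, p),
                   tolerance = 1e-12)
    }
  }
  p <- seq(0, 1, by = 0.05)
  expect_equal(predicted_activity(1, p), 1 - p, tolerance = 1e-12)
  expect_equal(predicted_activity(5, p), (1 - p)^5, tolerance = 1e-12)
  expect_error(predicted_activity(0, 0.5), "k_min")
  expect_error(predicted_activity(6, 0.5), "k_min")
})

test_that("activity curves are monotone in doping and ordered in k_min", {
  curves <- activity_curves(seq(0, 1, by = 0.02))
  for (km in 1:5) {
    a <- curves$activity[curves$k_min == km]
    expect_true(all(diff(a) <= 1e-12))
    expect_equal(a[1], 1)
  }
  interior <- curves$doping_p > 0 & curves$doping_p < 1
  wide <- tidyr::pivot_wider(curves[interior, ], names_from = "k_min",
                             values_from = "activity")
  for (km in 2:5) {
    expect_true(all(wide[[as.character(km)]] < wide[[as.character(km - 1)]]))
  }
})

test_that("k_min fitting recovers generating curves and breaks ties upward", {
  obs <- activity_curves(seq(0, 0.8, by = 0.2), k_min = 3)
  fit <- fit_kmin(obs)
  expect_equal(fit$k_min, 3)
  expect_equal(fit$rss$rss[3], 0, tolerance = 1e-20)

  lin <- tibble::tibble(doping_p = seq(0, 1, 0.25), activity = 1 - seq(0, 1, 0.25))
  expect_equal(fit_kmin(lin)$k_min, 1)

  # observations at p = 0 only match every curve: tie goes to the larger k_min
  tie <- tibble::tibble(doping_p = c(0, 0, 1e-9), activity = c(1, 1, 1))
  expect_equal(fit_kmin(tie)$k_min, 5)

  expect_error(fit_kmin(tibble::tibble(doping_p = c(0.2, 0.2),
                                       activity = c(0.5, 0.6))),
               "[Dd]egenerate")
})

test_that("k_min = 5 is recovered from noisy activity data in most replicates", {
  set.seed(42)
  p_grid <- c(0, 0.2, 0.4, 0.6, 0.8)
  truth <- predicted_activity(5, p_grid)
  hits <- replicate(500, {
    obs <- tibble::tibble(doping_p = p_grid,
                          activity = truth + rnorm(5, sd = 0.05))
    fit_kmin(obs)$k_min == 5
  })
  expect_gte(mean(hits), 0.9)
})
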