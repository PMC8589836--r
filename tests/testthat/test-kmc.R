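test_that("a slip-free motor packages monotonically at the closed-form rate", {
  cfg <- sim_config(p_pause_slip = 0, pre_packaged = 35)
  res <- simulate_packaging(cfg, n_traj = 3, seed = 1, keep_trajectory = TRUE)
  expect_true(all(res$outcome == "success"))
  for (i in 1:3) {
    traj <- res$trajectory[[i]]
    expect_true(all(diff(traj$unpackaged_bp) < 0))
  }
  # event count = distance / step size (final step may overshoot into <= 0)
  expect_true(all(abs(res$n_events - (3400 - 35) / 2) <= 1))
  # mean velocity approaches step_size / t_package_mean = 0.2 bp per arb unit
  expect_lt(abs(mean(res$mean_velocity) - 0.2), 0.01)
})

test_that("a fully inactive motor always fails", {
  for (rule in c("effective", "per_position")) {
    cfg <- sim_config(n_inactive = 5, p_pause_slip = 0.75, inactive_rule = rule)
    res <- simulate_packaging(cfg, n_traj = 5, seed = 2)
    expect_true(all(res$outcome == "failure"))
    expect_true(all(res$n_slip_events == res$n_events))
  }
})

test_that("empirical per-event drift matches the closed form at 3 sigma", {
  # huge DNA so no absorption interferes over 1e5 events
  configs <- list(
    sim_config(p_pause_slip = 0.65, dna_length = 1e7, pre_packaged = 5e6,
               max_events = 1e5),
    sim_config(p_pause_slip = 0.75, dna_length = 1e7, pre_packaged = 5e6,
               max_events = 1e5),
    sim_config(n_inactive = 1, p_pause_slip = 0.75, inactive_rule = "per_position",
               dna_length = 1e7, pre_packaged = 5e6, max_events = 1e5),
    sim_config(n_inactive = 2, p_pause_slip = 0.75, inactive_rule = "per_position",
               dna_length = 1e7, pre_packaged = 5e6, max_events = 1e5),
    sim_config(p_pause_slip = 0.65, slip_rounding = "round", dna_length = 1e7,
               pre_packaged = 5e6, max_events = 1e5)
  )
  for (k in seq_along(configs)) {
    cfg <- configs[[k]]
    res <- simulate_packaging(cfg, n_traj = 1, seed = 10 + k)
    expect_equal(res$outcome, "censored")
    drift_hat <- (res$unpackaged_final_bp - (cfg$dna_length - res$pre_packaged_bp)) /
      res$n_events * (-1)
    th <- kmc_expected_drift(cfg)
    # conservative bound: E[d^2] <= (1-p)*step^2 + p*2*mu^2 <= 4 here
    se_bound <- 2 / sqrt(res$n_events)
    expect_lt(abs(drift_hat - th$drift_bp_per_event), 3 * se_bound)
  }
})

test_that("per-position drift is zero for 1 inactive and negative for 2", {
  d1 <- kmc_expected_drift(sim_config(n_inactive = 1, p_pause_slip = 0.75,
                                      inactive_rule = "per_position"))
  d2 <- kmc_expected_drift(sim_config(n_inactive = 2, p_pause_slip = 0.75,
                                      inactive_rule = "per_position"))
  expect_equal(d1$drift_bp_per_event, 0, tolerance = 1e-12)
  expect_lt(d2$drift_bp_per_event, 0)
})

test_that("identical configs and seeds give bit-identical results", {
  cfg <- sim_config(n_inactive = 1, p_pause_slip = 0.75)
  a <- simulate_packaging(cfg, n_traj = 10, seed = 42)
  b <- simulate_packaging(cfg, n_traj = 10, seed = 42)
  expect_identical(a, b)
  a$condition <- b$condition <- "x"
  expect_identical(summarize_simulations(a), summarize_simulations(b))
})

test_that("success fraction is non-increasing in the number of inactive subunits", {
  # short tether keeps the zero-drift 1-inactive case tractable
  fr <- vapply(c(0, 1, 2, 5), function(ni) {
    cfg <- sim_config(n_inactive = ni, p_pause_slip = 0.75,
                      inactive_rule = "per_position", dna_length = 200,
                      pre_packaged = c(30, 40), max_events = 2e5)
    res <- simulate_packaging(cfg, n_traj = 150, seed = 7)
    mean(res$outcome == "success")
  }, numeric(1))
  expect_true(all(diff(fr) <= 0.05)) # allow Monte Carlo slack on the ordering
  expect_equal(fr[4], 0)
})

test_that("strict arrest abolishes packaging for doped motors only", {
  cfg1 <- sim_config(n_inactive = 1, p_pause_slip = 0.75)
  cmp <- coordination_scheme_compare(cfg1, n_traj = 60, seed = 8)
  expect_equal(cmp$success_fraction[cmp$condition == "strict_arrest"], 0)
  expect_gt(cmp$success_fraction[cmp$condition == "flexible_bypass"], 0)

  # with no inactive subunits the two schemes are the same process
  cfg0 <- sim_config(n_inactive = 0, p_pause_slip = 0.65)
  cfg0_strict <- `class<-`(modifyList(cfg0, list(scheme = "strict_arrest")),
                           "sim_config")
  flex <- simulate_packaging(cfg0, n_traj = 5, seed = 9)
  strict <- simulate_packaging(cfg0_strict, n_traj = 5, seed = 9)
  expect_equal(flex, strict, ignore_attr = TRUE)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_inactive = 6), "<=")
  expect_error(sim_config(p_pause_slip = 1.2), "0, 1")
  expect_error(sim_config(pre_packaged = c(50, 40)), "range")
  expect_error(sim_config(pre_packaged = 4000), "range")
  expect_error(summarize_simulations(NULL), "non-empty")
})
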