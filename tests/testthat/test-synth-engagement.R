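test_that("single-component gaps collapse to a plain exponential", {
  kin <- engagement_kinetics(amp_short = 1, tau_short = 5, amp_long = 0,
                             tau_long = 40)
  ev <- sample_engagement_events(kin, duration = 3e4, seed = 1)
  g <- ev$gap_before_s
  se <- sd(g) / sqrt(length(g))
  expect_lt(abs(mean(g) - 5), 3 * se)
  expect_true(all(ev$gap_component == "short"))
})

test_that("default gap mixture has an amplitude-weighted mean of 12 s", {
  kin <- engagement_kinetics()
  expect_equal(kin$amp_short * kin$tau_short + kin$amp_long * kin$tau_long, 12)
  ev <- sample_engagement_events(kin, duration = 1.2e5, seed = 2)
  g <- ev$gap_before_s
  se <- sd(g) / sqrt(length(g))
  expect_lt(abs(mean(g) - 12), 3 * se)
})

test_that("ground-truth events never overlap and respect the trace window", {
  for (seed in 1:10) {
    ev <- sample_engagement_events(engagement_kinetics(), 240, seed = seed)
    if (nrow(ev) < 2) next
    expect_true(all(ev$end_s > ev$start_s))
    expect_true(all(ev$start_s[-1] >= ev$end_s[-nrow(ev)]))
    expect_true(all(ev$end_s <= 240))
    expect_equal(ev$lifetime_s, ev$end_s - ev$start_s)
  }
})

test_that("observed lifetimes follow the bleach-censored mixture law", {
  kin <- engagement_kinetics()
  ev <- sample_engagement_events(kin, duration = 2e5, seed = 3)
  obs <- ev$lifetime_s[ev$end_reason != "censored_at_trace_end"]
  expect_gt(length(obs), 8000)
  ks <- suppressWarnings(ks.test(
    obs, function(t) 1 - censored_lifetime_survival(t, kin)
  ))
  expect_gt(ks$p.value, 0.01)

  # fraction of observed lifetimes > 10 s against the closed-form survival
  p10 <- censored_lifetime_survival(10, kin)
  se <- sqrt(p10 * (1 - p10) / length(obs))
  expect_lt(abs(mean(obs > 10) - p10), 3 * se)

  # end reasons: bleaching accounts for S_L-weighted share; sanity-check both occur
  expect_true(all(c("dissociation", "photobleach") %in% ev$end_reason))
})

test_that("trace rendering matches the event ground truth", {
  kin <- engagement_kinetics()
  sim <- gen_engagement_trajectory(kin, duration = 120, noise_sd = 0,
                                   n_traces = 3, seed = 4)
  for (id in 1:3) {
    tr <- sim$traces[sim$traces$trace_id == id, ]
    ev <- sim$events[sim$events$trace_id == id, ]
    engaged <- rep(FALSE, nrow(tr))
    for (j in seq_len(nrow(ev))) {
      engaged[tr$time_s >= ev$start_s[j] & tr$time_s < ev$end_s[j]] <- TRUE
    }
    expect_equal(tr$intensity_au, engaged * 1)
  }
  a <- gen_engagement_trajectory(kin, duration = 60, seed = 9)
  b <- gen_engagement_trajectory(kin, duration = 60, seed = 9)
  expect_identical(a, b)
  expect_error(gen_engagement_trajectory(kin, duration = -1), "duration")
  expect_error(gen_engagement_trajectory(kin, spike_amplitude = 0), "spike_amplitude")
})

test_that("kinetics constructor enforces mixture invariants", {
  expect_error(engagement_kinetics(amp_short = 0.5, amp_long = 0.6), "sum to 1")
  expect_error(engagement_kinetics(tau_short = 40, tau_long = 5), "exceed")
  expect_error(engagement_kinetics(lifetime_weights = c(0.5, 0.5)), "3 components")
})
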