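make_linear_trace <- function(v, duration = 2, dt = 0.005, noise = 0,
                              bp0 = 3400) {
  tms <- seq(0, duration, by = dt)
  bp <- bp0 - v * tms
  tibble::tibble(
    time_s = tms,
    extension_nm = extension_from_bp(bp, 5) +
      if (noise > 0) rnorm(length(tms), sd = noise) else 0,
    force_pN = 5
  )
}

test_that("rolling velocity reproduces a constant packaging rate exactly", {
  tr <- make_linear_trace(700)
  v <- rolling_velocity(tr)
  core <- !is.na(v$velocity_bp_s)
  expect_equal(unname(v$velocity_bp_s[core]), rep(700, sum(core)),
               tolerance = 1e-9)
})

test_that("rolling velocity of pure noise is centred on zero", {
  set.seed(1)
  tms <- seq(0, 5, by = 0.005)
  tr <- tibble::tibble(time_s = tms,
                       extension_nm = 1000 + rnorm(length(tms), sd = 2),
                       force_pN = 5)
  v <- rolling_velocity(tr)$velocity_bp_s
  v <- v[!is.na(v)]
  # thin to every window to de-correlate before the standard-error check
  vi <- v[seq(1, length(v), by = 21)]
  expect_lt(abs(mean(vi)), 3 * sd(vi) / sqrt(length(vi)))
  expect_error(rolling_velocity(tr[1:5, ], window = 0.1), "window")
})

test_that("injected plateau pauses are detected with window-level boundaries", {
  # trace built from an explicit velocity profile with two 0.4-s plateaus
  tms <- seq(0, 3.4, by = 0.005)
  t1 <- c(0.8, 1.2); t2 <- c(2.0, 2.4)
  in1 <- tms >= t1[1] & tms < t1[2]
  in2 <- tms >= t2[1] & tms < t2[2]
  vel <- ifelse(in1 | in2, 0, 960)
  bp2 <- 3400 - cumsum(vel) * 0.005
  set.seed(3)
  tr2 <- tibble::tibble(
    time_s = tms,
    extension_nm = extension_from_bp(bp2, 5) + rnorm(length(bp2), sd = 2),
    force_pN = 5
  )
  v <- rolling_velocity(tr2)
  pauses <- detect_pauses(v)
  expect_equal(nrow(pauses), 2L)
  expect_lt(abs(pauses$start_s[1] - t1[1]), 0.1 + 1e-9)
  expect_lt(abs(pauses$end_s[1] - t1[2]), 0.1 + 1e-9)
  expect_lt(abs(pauses$start_s[2] - t2[1]), 0.1 + 1e-9)
  expect_lt(abs(pauses$end_s[2] - t2[2]), 0.1 + 1e-9)
  expect_equal(classify_pause(pauses$pause_velocity_bp_s),
               c("plateau", "plateau"))
})

test_that("interruptions at or below 0.1 s are not reported as pauses", {
  tms <- seq(0, 3, by = 0.005)
  bp <- 3400 - cumsum(rep(960 * 0.005, length(tms)))
  # 0.05-s interruption
  stall <- tms >= 1.5 & tms < 1.55
  bp[stall] <- bp[which(stall)[1]]
  bp[tms >= 1.55] <- bp[tms >= 1.55] + 960 * 0.05
  tr <- tibble::tibble(time_s = tms, extension_nm = extension_from_bp(bp, 5),
                       force_pN = 5)
  v <- rolling_velocity(tr)
  expect_equal(nrow(detect_pauses(v)), 0L)
})

test_that("false-positive pause rate on pause-free traces is at most 0.1/trace", {
  p <- trap_sim_params(pause_rate = 0, noise_sd = 2)
  n_fp <- 0L
  for (i in 1:60) {
    sim <- gen_extension_trace(p, n_traces = 1, seed = 100 + i)
    v <- rolling_velocity(sim$traces)
    n_fp <- n_fp + nrow(detect_pauses(v))
  }
  expect_lte(n_fp / 60, 0.1)
})

test_that("pause classification separates plateaus from unpackaging", {
  expect_equal(classify_pause(0), "plateau")
  expect_equal(classify_pause(-300), "unpackaging")
  expect_equal(classify_pause(-20), "plateau")
  expect_warning(out <- classify_pause(120), "plateau band")
  expect_equal(out, "contradiction")
})

test_that("trace metrics: catenated velocity, pause frequency, start time", {
  # ground-truth pauses from the generator feed the metric arithmetic
  p <- trap_sim_params(start_delay_s = 3)
  sim <- gen_extension_trace(p, n_traces = 1, seed = 4)
  v <- rolling_velocity(sim$traces)
  pauses <- detect_pauses(v)
  m <- trace_metrics(sim$traces, pauses)
  expect_lt(abs(m$start_time_s - 3), 0.25)
  expect_lt(abs(m$pause_free_velocity_bp_s - 960) / 960, 0.05)
  expect_gt(m$total_packaged_bp, 3200)

  # frequency arithmetic on a hand-built pause table
  tms <- seq(0, 3400 * 0.4 / 960, by = 0.005)
  tr <- make_linear_trace(960, duration = max(tms))
  fake <- tibble::tibble(start_s = c(0.3, 0.6, 0.9), end_s = c(0.45, 0.75, 1.05),
                         duration_s = rep(0.15, 3))
  mm <- trace_metrics(tr, fake)
  expect_equal(mm$n_pauses, 3)
  # ~2.5 kb are packaged over this trace: 3 pauses -> ~1.2 per kb
  expect_lt(abs(mm$pause_frequency_per_kb - 3 / (mm$total_packaged_bp / 1000)),
            1e-9)
})

test_that("pause-free velocity recovery is unbiased across 100-2000 bp/s", {
  set.seed(5)
  errs <- vapply(1:40, function(i) {
    vtrue <- runif(1, 100, 2000)
    sim <- gen_extension_trace(trap_sim_params(pause_free_velocity = vtrue),
                               n_traces = 1, seed = 300 + i)
    v <- rolling_velocity(sim$traces)
    m <- trace_metrics(sim$traces, detect_pauses(v))
    (m$pause_free_velocity_bp_s - vtrue) / vtrue
  }, numeric(1))
  expect_lt(median(abs(errs)), 0.05)
})

test_that("pause and packaging time partition the trace", {
  p <- trap_sim_params(pause_rate = 2)
  sim <- gen_extension_trace(p, n_traces = 1, seed = 6)
  v <- rolling_velocity(sim$traces)
  pauses <- detect_pauses(v)
  total <- max(sim$traces$time_s)
  expect_lt(sum(pauses$duration_s), total)
  # detected pauses never overlap
  if (nrow(pauses) > 1) {
    expect_true(all(pauses$start_s[-1] >= pauses$end_s[-nrow(pauses)]))
  }
  # zero-pause metrics
  sim0 <- gen_extension_trace(trap_sim_params(pause_rate = 0, noise_sd = 2),
                              n_traces = 1, seed = 7)
  m0 <- trace_metrics(sim0$traces, detect_pauses(rolling_velocity(sim0$traces)))
  expect_equal(m0$pause_frequency_per_kb, 0)
  expect_true(is.na(m0$mean_pause_duration_s))
})
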