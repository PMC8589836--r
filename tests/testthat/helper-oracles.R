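# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force enumeration for the coordination
# model, a plain sequential sampler for the engagement process, and
# closed-form censoring laws.

# Ensemble activity by enumeration of all 2^n subunit configurations.
brute_force_activity <- function(k_min, doping_p, n = 5) {
  states <- as.matrix(expand.grid(rep(list(c(0L, 1L)), n))) # 1 = active
  k <- rowSums(states)
  pr <- (1 - doping_p)^k * doping_p^(n - k)
  sum(ifelse(k >= k_min, k / n, 0) * pr)
}

# Direct sequential simulation of the engagement process (gap mixture +
# lifetime mixture + exponential photobleach censoring), written without
# reference to the package generator.
direct_engagement_sim <- function(kin, duration) {
  t <- 0
  out <- list()
  repeat {
    g <- if (runif(1) < kin$amp_long) rexp(1, 1 / kin$tau_long) else rexp(1, 1 / kin$tau_short)
    s <- t + g
    if (s >= duration) break
    comp <- sample.int(3L, 1L, prob = kin$lifetime_weights)
    life <- rexp(1, 1 / kin$lifetime_taus[comp])
    bleach <- rexp(1, 1 / kin$bleach_lifetime)
    e <- min(s + min(life, bleach), duration)
    out[[length(out) + 1L]] <- c(start = s, end = e,
                                 censored = as.numeric(s + min(life, bleach) > duration))
    t <- e
    if (s + min(life, bleach) > duration) break
  }
  do.call(rbind, out)
}

# Survival function of the observed (bleach-censored) engagement lifetime:
# P(min(L, B) > t) with L the lifetime mixture and B exponential.
censored_lifetime_survival <- function(t, kin) {
  sapply(t, function(tt) {
    sum(kin$lifetime_weights * exp(-tt / kin$lifetime_taus)) *
      exp(-tt / kin$bleach_lifetime)
  })
}

# Build a noiseless staircase trace on a 0.1-s grid; `len_frames` is either
# one common length or one length per level.
staircase_trace <- function(levels, len_frames, frame = 0.1, noise_sd = 0) {
  if (length(len_frames) == 1L) len_frames <- rep(len_frames, length(levels))
  x <- rep(levels, times = len_frames)
  tibble::tibble(
    time_s = seq(0, by = frame, length.out = length(x)),
    intensity_au = x + if (noise_sd > 0) rnorm(length(x), sd = noise_sd) else 0
  )
}
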