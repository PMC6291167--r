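make_ts <- function(x, fs = 100, run = 1L) {
  pupil_ts(seq(0, by = 1 / fs, length.out = length(x)), x, fs, run)
}

test_that("blink interpolation restores flat and linear signals exactly", {
  fs <- 100
  ramp <- seq(0, 10, length.out = 10 * fs)
  ts <- make_ts(ramp, fs)
  gap <- data.frame(start = 4, end = 4.5)
  damaged <- ts
  damaged$diameter[ts$time >= 4 & ts$time <= 4.5] <- 0
  fixed <- interpolate_blinks(damaged, gap)
  expect_equal(fixed$diameter, ramp, tolerance = 1e-10)
  flat <- make_ts(rep(3, 500), fs)
  flat$diameter[200:240] <- NA
  fixed2 <- interpolate_blinks(flat, data.frame(start = 2, end = 2.4))
  expect_equal(fixed2$diameter, rep(3, 500))
  expect_false(anyNA(fixed2$diameter))
  # idempotence: re-running on clean output changes nothing
  expect_equal(interpolate_blinks(fixed, gap)$diameter, fixed$diameter)
})

test_that("interpolation over planted blinks stays below the noise floor", {
  set.seed(14)
  fs <- 100
  t <- seq(0, 60, by = 1 / fs)
  clean <- sin(2 * pi * 0.2 * t) + 0.1 * rnorm(length(t))
  blinks <- data.frame(start = c(5, 15, 28, 40, 52))
  blinks$end <- blinks$start + 0.15
  dirty <- clean
  for (i in 1:5) dirty[t >= blinks$start[i] & t <= blinks$end[i]] <- -4
  fixed <- interpolate_blinks(pupil_ts(t, dirty, fs), blinks)
  expect_lt(sqrt(mean((fixed$diameter - clean)^2)), 0.1)
})

test_that("residual blink detection flags only fast transients", {
  set.seed(15)
  fs <- 100
  smooth <- make_ts(sin(2 * pi * 0.5 * seq(0, 30, by = 1 / fs)) +
                      0.05 * rnorm(3001), fs)
  smooth <- pupil_bandpass(smooth, 0.05, 4)
  expect_equal(nrow(detect_residual_blinks(smooth)), 0L)
  expect_equal(nrow(detect_residual_blinks(make_ts(rep(1, 1000), fs))), 0L)
  # planted step of ten robust SDs of the first difference
  x <- smooth$diameter
  s <- mad(diff(x))
  x[1500:1560] <- x[1500:1560] - 10 * s * 15
  det <- detect_residual_blinks(make_ts(x, fs))
  expect_gt(nrow(det), 0L)
  expect_true(any(det$start <= 15.0 & det$end >= 14.98))
})

test_that("band-pass has the specified frequency response", {
  fs <- 100
  t <- seq(0, 300, by = 1 / fs)
  mid <- t > 60 & t < 240   # avoid edges when measuring gain
  slow <- make_ts(sin(2 * pi * 0.01 * t), fs)
  out_slow <- pupil_bandpass(slow, 0.05, 4)
  expect_lt(sd(out_slow$diameter[mid]) / sd(slow$diameter[mid]), 0.1)
  fast <- make_ts(sin(2 * pi * 1 * t), fs)
  out_fast <- pupil_bandpass(fast, 0.05, 4)
  expect_lt(abs(sd(out_fast$diameter[mid]) / sd(fast$diameter[mid]) - 1),
            0.05)
  const <- make_ts(rep(5, 3000), fs)
  expect_lt(max(abs(pupil_bandpass(const, 0.05, 4)$diameter)), 1e-8)
  expect_error(pupil_bandpass(make_ts(rnorm(100), 6), 0.05, 4), "twice")
})

test_that("band-pass plus z-score is invariant to affine input transforms", {
  set.seed(16)
  fs <- 100
  x <- cumsum(rnorm(20 * fs)) / 10
  a <- zscore_resample(pupil_bandpass(make_ts(x, fs)), 20)
  b <- zscore_resample(pupil_bandpass(make_ts(7.5 * x + 120, fs)), 20)
  expect_equal(a$diameter, b$diameter, tolerance = 1e-9)
})

test_that("z-scoring and resampling meet their contracts", {
  set.seed(17)
  fs <- 1000
  x <- rnorm(60 * fs)
  ts <- make_ts(x, fs)
  out <- zscore_resample(ts, 20)
  expect_equal(nrow(out), 1200L)     # 60 s at 20 Hz
  expect_equal(attr(out, "fs"), 20)
  # standardisation exact before decimation
  same_rate <- zscore_resample(make_ts(5 + 3 * x[1:5000], 100), 100)
  expect_lt(abs(mean(same_rate$diameter)), 1e-6)
  expect_lt(abs(sd(same_rate$diameter) - 1), 1e-6)
  # two runs with different gains give identical standardised stats
  two <- pupil_ts(c(seq(0, 9.99, 0.01), seq(10, 19.99, 0.01)),
                  c(x[1:1000], 40 * x[1001:2000] + 7), 100,
                  rep(1:2, each = 1000))
  z2 <- zscore_resample(two, 20)
  m <- tapply(z2$diameter, z2$run, mean)
  expect_true(all(abs(m) < 0.05))
  expect_error(zscore_resample(make_ts(rep(1, 100), 100), 20), "variance")
  expect_error(zscore_resample(make_ts(rnorm(100), 30), 20), "multiple")
})

test_that("pupil IRF peaks at t_max with unit amplitude", {
  tt <- seq(0, 4, by = 0.001)
  h <- pupil_irf(tt)
  expect_equal(max(h), 1, tolerance = 1e-6)
  expect_equal(tt[which.max(h)], 0.93, tolerance = 0.002)
  expect_true(all(pupil_irf(seq(-1, 0, 0.1)) == 0))
})

test_that("nuisance regression removes planted blink responses", {
  set.seed(18)
  fs <- 20
  t <- seq(0, 120, by = 1 / fs)
  blink_ends <- c(10, 25, 42, 60, 83, 101)
  kernel <- pupil_irf(seq(0, 4, by = 1 / fs))
  stick <- numeric(length(t))
  stick[round(blink_ends * fs) + 1] <- 1
  resp <- -0.8 * stats::filter(stick, kernel, sides = 1)
  resp[is.na(resp)] <- 0
  # pure nuisance train: residuals collapse to ~0
  pure <- pupil_ts(t, as.numeric(resp), fs)
  res_pure <- remove_nuisance(pure, blink_times = blink_ends)
  expect_lt(sd(res_pure$diameter), 0.02 * sd(pure$diameter))
  # no events: identity
  noisy <- pupil_ts(t, as.numeric(resp) + 0.3 * rnorm(length(t)), fs)
  expect_equal(remove_nuisance(noisy)$diameter, noisy$diameter)
  # planted responses + white noise: variance reduced, gain recovered
  res <- remove_nuisance(noisy, blink_times = blink_ends)
  expect_lt(var(res$diameter), var(noisy$diameter))
  expect_lt(abs(attr(res, "nuisance_betas")[["blink"]] - (-0.8)), 0.08)
})

test_that("trial rejection applies saccade and RT rules", {
  cfg <- task_config(n_runs_learning = 1, trials_per_run = 30,
                     n_runs_transfer = 0)
  sim <- simulate_agent(agent_params(0.4, 0.2, 10), cfg, seed = 51)
  trials <- sim$trials
  expect_equal(reject_trials(trials, NULL)$fraction_rejected, 0)
  # one large saccade inside trial 5's decision interval
  sac <- data.frame(time = (trials$t_options_on[5] + trials$t_choice[5]) / 2,
                    amplitude = 4)
  rej <- reject_trials(trials, sac)
  expect_equal(rej$rejected, 5L)
  # sub-threshold saccades never reject
  sac_small <- data.frame(time = sac$time, amplitude = 2.0)
  expect_equal(reject_trials(trials, sac_small)$fraction_rejected, 0)
  # RT bounds
  trials2 <- trials
  trials2$rt[c(2, 9)] <- c(0.05, 3.8)
  expect_equal(reject_trials(trials2, NULL)$rejected, c(2L, 9L))
})

test_that("planted violation rate is recovered on a synthetic session", {
  set.seed(52)
  cfg <- task_config(n_runs_learning = 4, trials_per_run = 60,
                     n_runs_transfer = 0)
  sim <- simulate_agent(agent_params(0.4, 0.2, 10), cfg, seed = 52)
  trials <- sim$trials
  viol <- runif(nrow(trials)) < 0.05
  sac <- data.frame(time = (trials$t_options_on[viol] +
                              trials$t_choice[viol]) / 2,
                    amplitude = 5)
  rej <- reject_trials(trials, sac)
  expect_equal(rej$fraction_rejected, mean(viol), tolerance = 1e-12)
})
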