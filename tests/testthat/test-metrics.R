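fs <- 16000

test_that("rolling strength uses a 20-sample window with NA edges", {
  s <- rolling_strength(numeric(160), fs)
  expect_identical(sum(is.na(s)), 19L)        # 10 leading + 9 trailing
  expect_true(all(s[!is.na(s)] == 0))         # constant waveform
  # the baseline read-out at -1.875 ms covers exactly -2.5..-1.25 ms
  x <- c(rep(1, 20), numeric(140))
  time <- ((1:160) - 41) / fs
  i <- which.min(abs(time + 1.875e-3))
  expect_identical(i, 11L)
  expect_identical(rolling_strength(x, fs)[11], 0)  # window is all ones
})

test_that("rolling strength is offset-invariant and scale-equivariant", {
  set.seed(5)
  x <- stats::rnorm(500)
  s <- rolling_strength(x, fs)
  expect_equal(rolling_strength(x + 3.7, fs), s)
  expect_equal(rolling_strength(-2.5 * x, fs), 2.5 * s)
  expect_error(rolling_strength(stats::rnorm(10), fs), "longer than")
})

test_that("a unit step peaks the rolling SD at the step with value sqrt(5/19)", {
  x <- c(numeric(200), rep(1, 200))
  s <- rolling_strength(x, fs)
  expect_identical(which.max(s), 201L)  # window: 10 zeros, 10 ones
  expect_equal(s[201], sqrt(5 / 19))
})

test_that("mean rolling strength of white noise approaches its SD", {
  set.seed(11)
  sigma <- 2.3e-6
  s <- rolling_strength(stats::rnorm(40000, sd = sigma), fs)
  # E[sample SD] = c4(20) * sigma = 0.987 * sigma
  expect_equal(mean(s, na.rm = TRUE), sigma, tolerance = 0.03)
})

test_that("threshold interpolation is linear between bracketing levels", {
  est <- estimate_threshold(c(33, 37), c(0.25e-6, 0.35e-6))
  expect_equal(est$threshold, 35)
  expect_identical(est$censoring, "none")
  # exact criterion hit lands on the tested level
  est <- estimate_threshold(c(29, 33, 37), c(0.1e-6, 0.3e-6, 0.9e-6))
  expect_equal(est$threshold, 33)
  # multiple crossings: the highest-level one wins
  est <- estimate_threshold(seq(25, 41, 4),
                            c(0.5, 0.2, 0.4, 0.25, 0.8) * 1e-6)
  expect_equal(est$threshold, 37 + 0.05 / 0.55 * 4, tolerance = 1e-9)
  expect_equal(est$crossing_levels, c(37, 41))
})

test_that("thresholds censor when the criterion is never or always reached", {
  g <- seq(25, 73, 4)
  always <- estimate_threshold(g, rep(1e-6, 13))
  expect_identical(always$censoring, "below_grid")
  expect_equal(always$threshold, 25)
  never <- estimate_threshold(g, rep(0.1e-6, 13))
  expect_identical(never$censoring, "above_grid")
  expect_equal(never$threshold, 73)
  expect_error(estimate_threshold(33, 1e-6), "at least 2")
})

test_that("raising strengths can only lower the interpolated threshold", {
  g <- seq(25, 73, 4)
  set.seed(21)
  for (i in 1:30) {
    s <- cumsum(stats::runif(13, 0, 0.2e-6))  # nondecreasing strengths
    bump <- stats::runif(13, 0, 0.1e-6)
    a <- estimate_threshold(g, s)
    b <- estimate_threshold(g, s + bump)
    expect_lte(b$threshold, a$threshold + 1e-9)
  }
})

test_that("the primary peak is found to sub-sample precision", {
  time <- ((1:160) - 41) / fs
  spec <- abr_kernel_spec()  # extremum at 1.4 ms, off the 62.5 us grid
  g <- 3e-6 * abrkit:::abr_kernel(time, spec, 73, 73)
  pk <- find_primary_peak(g, time)
  expect_true(pk$found)
  expect_lt(abs(pk$latency - 1.4e-3), 2e-5)
  expect_lt(abs(pk$amplitude - (-3e-6)), 0.05e-6)
  # a purely positive deflection has no negative peak
  bump <- 3e-6 * exp(-(time - 1.4e-3)^2 / (2 * 2.5e-7))
  expect_false(find_primary_peak(bump, time)$found)
  expect_true(find_primary_peak(-bump, time)$found)
  # latency error under 1 sample with noise at ~3% of the peak
  set.seed(3)
  err <- replicate(20, {
    pkn <- find_primary_peak(g + stats::rnorm(160, sd = 0.1e-6), time)
    abs(pkn$latency - 1.4e-3)
  })
  expect_lt(stats::median(err), 1 / fs)
})

test_that("cross-correlation lags recover imposed shifts and the latency slope", {
  time <- ((1:160) - 41) / fs
  spec <- abr_kernel_spec()
  base <- abrkit:::abr_kernel(time, spec, 73, 73)
  levels <- seq(49, 73, 4)
  m <- array(NA_real_, dim = c(7, 160, 1),
             dimnames = list(as.character(levels), NULL, "LV"))
  for (i in 1:7) m[i, , 1] <- base
  avg <- structure(list(mean = m, levels = levels, time = time,
                        sampling_rate = fs, n_trials = rep(1, 7),
                        baseline_rms = matrix(0, 7, 1),
                        metadata = list()),
                   class = "averaged_abr")
  # identical waveforms: zero slope
  expect_equal(latency_shift(avg)$slope_s_per_db, 0, tolerance = 1e-12)
  # a 2-sample integer shift is a 125 us lag
  shifted <- avg
  shifted$mean["49", , 1] <- c(numeric(2), base[1:158])
  expect_lt(abs(latency_shift(shifted)$table$lag_s[1] - 125e-6), 3e-6)
  # continuous-time shifts at the generator's 6.9 us/dB are recovered
  m2 <- m
  for (i in 1:7) {
    g <- abrkit:::abr_kernel(time, spec, levels[i], 73)
    g[time < 0] <- 0
    m2[i, , 1] <- g
  }
  avg$mean <- m2
  expect_lt(abs(latency_shift(avg)$slope_s_per_db - 6.9e-6), 0.2e-6)
})

test_that("session waveforms correlate within and across subjects", {
  day1 <- healthy_result()$averaged[[1]]
  wc <- waveform_correlation(list(day1), list(day1),
                             subjects1 = "m1", subjects2 = "m1")
  expect_equal(unname(wc$within["mean"]), 1)
  # a negated waveform anticorrelates
  neg <- day1
  neg$mean <- -neg$mean
  wc <- waveform_correlation(list(day1), list(neg),
                             subjects1 = "m1", subjects2 = "m1")
  expect_equal(unname(wc$within["mean"]), -1)
  # independent noise, same kernel: high but imperfect repeat reliability
  day2 <- run_pipeline(generate_session(
    synth_config(seed = 77, duration = 120)))$averaged[[1]]
  wc <- waveform_correlation(list(day1), list(day2),
                             subjects1 = "m1", subjects2 = "m1")
  expect_gt(unname(wc$within["mean"]), 0.9)
  expect_lt(unname(wc$within["mean"]), 1)
})

test_that("threshold shifts aggregate per subject with censoring as bounds", {
  pre <- data.frame(subject = rep(c("a", "b"), each = 2),
                    threshold_db = c(34, 36, 33, 35))
  post <- data.frame(subject = c("a", "b"),
                     threshold_db = c(60, 59),
                     censoring = c("none", "none"))
  ts <- threshold_shift(pre, post)
  expect_equal(ts$per_subject$shift_db, c(25, 25))
  expect_equal(ts$mean_shift_db, 25)
  expect_equal(ts$sd_shift_db, 0)
  expect_false(ts$lower_bound)
  # identical pre/post: zero shift
  expect_equal(threshold_shift(pre, pre)$mean_shift_db, 0)
  # censored post makes the shift a lower bound
  post$censoring <- c("above_grid", "none")
  expect_true(threshold_shift(pre, post)$lower_bound)
  expect_error(threshold_shift(pre, post[2, ]), "differ")
})

test_that("baseline noise declines as n^(-1/2) for independent trials", {
  tensor <- gaussian_tensor(300, sigma = 1.5e-6, seed = 14)
  curve <- noise_floor_curve(tensor, n_resample = 48)
  expect_equal(curve$slope, -0.5, tolerance = 0.05)
  # sigma / sqrt(n) at n = 100: about 0.15 uV
  r100 <- noise_floor_curve(tensor, n_grid = 100, n_resample = 64)
  expect_equal(r100$table$rms, 1.5e-6 / 10, tolerance = 0.15)
  # fully correlated trials: flat curve
  tensor$epochs[] <- rep(tensor$epochs[1, , 1], each = 300)
  flat <- noise_floor_curve(tensor)
  expect_equal(flat$slope, 0, tolerance = 1e-6)
  expect_warning(noise_floor_curve(gaussian_tensor(40), n_grid = c(8, 64)),
                 "truncated")
})
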