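fs <- 16000

test_that("the ABR band passes 1 kHz, kills DC and attenuates 60 Hz by 20 dB", {
  t <- (0:(4 * fs - 1)) / fs
  mid <- (fs):(3 * fs)  # avoid filter edge transients
  y1k <- abrkit:::band_filter(sin(2 * pi * 1000 * t), fs, 300, 3000)
  expect_equal(max(abs(y1k[mid])), 1, tolerance = 0.05)
  y60 <- abrkit:::band_filter(sin(2 * pi * 60 * t), fs, 300, 3000)
  expect_lt(max(abs(y60[mid])), 10^(-20 / 20))
  ydc <- abrkit:::band_filter(rep(0.5, length(t)), fs, 300, 3000)
  expect_lt(max(abs(ydc[mid])), 1e-6)
})

test_that("filtering is linear and rejects bands at or above Nyquist", {
  set.seed(2)
  x <- stats::rnorm(8000)
  y <- stats::rnorm(8000)
  lhs <- abrkit:::band_filter(2 * x - 3 * y, fs, 300, 3000)
  rhs <- 2 * abrkit:::band_filter(x, fs, 300, 3000) -
    3 * abrkit:::band_filter(y, fs, 300, 3000)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  rec <- abr_recording(cbind(LV = x), fs)
  expect_error(bandpass_filter(rec, 300, 9000), "Nyquist")
})

test_that("bandpass_filter leaves the speaker channel untouched", {
  s <- generate_session(synth_config(seed = 3, duration = 12))
  filt <- bandpass_filter(s$recording)
  expect_identical(channel(filt, "speaker"), channel(s$recording, "speaker"))
  expect_false(identical(channel(filt, "LV"), channel(s$recording, "LV")))
})

test_that("ECG beats are detected at the simulated heart rate", {
  s <- generate_session(synth_config(seed = 13, duration = 30))
  ecg <- detect_ecg(s$recording)
  expect_length(ecg$beats, length(s$manifest$beat_times))
  true_rate <- (length(s$manifest$beat_times) - 1) /
    diff(range(s$manifest$beat_times))
  expect_equal(ecg$heart_rate, true_rate, tolerance = 0.02)
  # template is peak-aligned: its extremum sits at the center sample
  expect_equal(which.max(abs(ecg$template)),
               (length(ecg$template) + 1) / 2)
  # pure noise has no beats
  quiet <- generate_session(noise_config(seed = 13, n_trials = 50))
  expect_warning(empty <- detect_ecg(quiet$recording), "no heartbeats")
  expect_length(empty$beats, 0)
})

test_that("epochs span -2.5 to +7.5 ms (160 samples at 16 kHz)", {
  s <- generate_session(synth_config(seed = 3, duration = 12))
  tensor <- epoch_trials(bandpass_filter(s$recording), s$stimulus)
  expect_identical(dim(tensor$epochs)[2], 160L)
  expect_identical(sum(tensor$time < 0), 40L)
  expect_identical(sum(tensor$time >= 0), 120L)
  expect_equal(tensor$time[41], 0)
  expect_equal(tensor$labels$level, s$stimulus$nominal_level_db)
  # epoch content matches a direct slice of the filtered recording
  filt <- bandpass_filter(s$recording)
  o <- s$stimulus$onset_sample[3]
  expect_equal(tensor$epochs[3, , "LV"],
               channel(filt, "LV")[(o - 40):(o + 119)])
})

test_that("clicks whose epoch window leaves the recording are clipped", {
  rec <- abr_recording(cbind(LV = stats::rnorm(160)), fs)
  stim <- data.frame(onset_sample = c(1L, 41L, 150L),
                     polarity = c(1L, 1L, -1L),
                     nominal_level_db = c(73, 73, 73))
  tensor <- epoch_trials(rec, stim)
  expect_identical(dim(tensor$epochs)[1], 1L)  # only onset 41 fits
  expect_identical(tensor$n_clipped, 2L)
  expect_error(epoch_trials(rec, stim[c(1, 3), ]), "no complete trials")
})

test_that("identical trials are never rejected and gross outliers always are", {
  e <- array(rep(sin(2 * pi * (1:160) / 20), each = 50),
             dim = c(50, 160, 1), dimnames = list(NULL, NULL, "LV"))
  tensor <- gaussian_tensor(50)
  tensor$epochs <- e
  expect_true(all(reject_outliers(tensor)$include))
  tensor <- gaussian_tensor(100, seed = 8)
  tensor$epochs[37, , 1] <- tensor$epochs[37, , 1] * 100
  out <- reject_outliers(tensor)
  expect_false(out$include[37])
  expect_true(all(out$include[-37]))
  expect_true(37 %in% attr(out, "rejection")$trial)
  expect_error(reject_outliers(gaussian_tensor(2)), "at least 3")
})

test_that("rejection is permutation-equivariant", {
  tensor <- gaussian_tensor(80, seed = 4)
  tensor$epochs[c(5, 60), , 1] <- tensor$epochs[c(5, 60), , 1] * 30
  mask <- reject_outliers(tensor)$include
  set.seed(9)
  perm <- sample(80)
  shuffled <- tensor
  shuffled$epochs <- tensor$epochs[perm, , , drop = FALSE]
  shuffled$labels <- tensor$labels[perm, ]
  expect_identical(reject_outliers(shuffled)$include, mask[perm])
})

test_that("injected artifact trials are rejected with few false positives", {
  s <- generate_session(noise_config(seed = 31, n_trials = 200))
  s <- inject_outlier_trials(s, 5, scale = 10)
  tensor <- reject_outliers(epoch_trials(bandpass_filter(s$recording),
                                         s$stimulus))
  rejected <- which(!tensor$include)
  expect_true(all(s$manifest$outlier_trials %in% rejected))
  false_pos <- setdiff(rejected, s$manifest$outlier_trials)
  expect_lt(length(false_pos) / (200 - 5), 0.02)
})

test_that("noiseless trials average to the trial waveform itself", {
  g <- abrkit:::abr_kernel(((1:160) - 41) / fs, abr_kernel_spec(), 73, 73)
  tensor <- gaussian_tensor(20)
  tensor$epochs <- array(rep(g, each = 20), dim = c(20, 160, 1),
                         dimnames = list(NULL, NULL, "LV"))
  avg <- average_by_level(tensor)
  expect_equal(avg$mean["73", , "LV"], g)
  expect_identical(avg$n_trials, 20L)
})

test_that("averaging 100 noisy trials brings the baseline near the 1/sqrt(n) floor", {
  tensor <- gaussian_tensor(100, sigma = 1.5e-6, seed = 6)
  avg <- average_by_level(tensor)
  expect_lt(avg$baseline_rms["73", "LV"], 0.25e-6)
  expect_gt(avg$baseline_rms["73", "LV"], 0.05e-6)
})

test_that("balanced polarity pooling cancels a sign-flipping artifact exactly", {
  art <- numeric(160)
  art[41] <- 5e-6
  tensor <- gaussian_tensor(90, sigma = 0)  # 45 of each polarity... n odd
  pol <- tensor$labels$polarity
  for (i in seq_len(90)) {
    tensor$epochs[i, , 1] <- tensor$epochs[i, , 1] + pol[i] * art
  }
  # drop one trial so the polarity counts are unbalanced (45 vs 44)
  tensor$include[1] <- FALSE
  avg <- average_by_level(tensor, by_polarity = TRUE)
  expect_lt(max(abs(avg$mean["73", , "LV"])), 1e-18)
  d <- avg$polarity["73", , "LV", "1"] - avg$polarity["73", , "LV", "-1"]
  expect_equal(max(abs(d)), 2 * 5e-6)
})

test_that("averaged channels obey LR = LV - RV at every level", {
  avg <- healthy_result()$averaged[[1]]
  d <- avg$mean[, , "LR"] - (avg$mean[, , "LV"] - avg$mean[, , "RV"])
  expect_lt(max(abs(d)), 1e-10)
})

test_that("an empty level cell is omitted with a warning", {
  tensor <- gaussian_tensor(30)
  tensor$labels$level[1:5] <- 41
  tensor$include[1:5] <- FALSE
  expect_warning(avg <- average_by_level(tensor), "omitted")
  expect_identical(rownames(avg$baseline_rms), "73")
})
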