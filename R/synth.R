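#' ABR wavelet specification
#'
#' The synthetic evoked response is a damped-cosine (Gabor-like) wavelet:
#' a ~1 kHz oscillation under a Gaussian envelope whose most negative
#' extremum sits at `primary_peak_latency` (negative because the ear
#' electrode is the non-inverting input). Below the loudest level the
#' wavelet is delayed by `latency_slope` seconds per dB.
#'
#' Response magnitude follows a softplus of level above
#' `true_threshold_db`, calibrated so that the scalar response strength
#' (rolling 1.25 ms SD at t = 2 ms) of the noiseless wavelet equals
#' `top_strength` at the loudest tested level. This places the strength-
#' vs-level curve's crossing of the 0.3 uV criterion within ~2 dB of
#' `true_threshold_db`, which is what the parameter-recovery tests exploit.
#'
#' @param primary_peak_latency seconds; latency of the negative peak at the
#'   loudest level.
#' @param oscillation_period seconds (carrier period).
#' @param envelope_sigma seconds (Gaussian envelope SD).
#' @param latency_slope seconds of added delay per dB below the loudest
#'   level.
#' @param true_threshold_db softplus threshold parameter, dB SPL.
#' @param softplus_width_db softplus width, dB.
#' @param top_strength target scalar strength at the loudest level, volts.
#' @param interaural_delay extra latency of the right-ear source, seconds.
#' @param right_gain right-ear source gain relative to left.
#' @param amplitude_scale overall multiplier (0 disables the response).
#' @return an object of class `abr_kernel_spec`.
#' @export
abr_kernel_spec <- function(primary_peak_latency = 1.4e-3,
                            oscillation_period = 1e-3,
                            envelope_sigma = 5e-4,
                            latency_slope = 6.9e-6,
                            true_threshold_db = 35,
                            softplus_width_db = 4,
                            top_strength = 3.45e-6,
                            interaural_delay = 3e-5,
                            right_gain = 0.9,
                            amplitude_scale = 1) {
  stopifnot(primary_peak_latency > 0, oscillation_period > 0,
            envelope_sigma > 0, latency_slope >= 0,
            softplus_width_db > 0, top_strength >= 0, amplitude_scale >= 0)
  structure(as.list(environment()), class = "abr_kernel_spec")
}

#' Synthetic ECG specification
#'
#' Heartbeats are a fixed biphasic (Ricker) template repeated at
#' `rate` Hz with uniform jitter on the beat-to-beat interval. The
#' template is scaled so its peak magnitude after 300-3000 Hz filtering
#' (the ABR analysis band) on the most affected channel equals
#' `amplitude`.
#'
#' @param rate beats per second (murine anesthetized heart: 3-4 Hz).
#' @param amplitude ABR-band peak amplitude, volts.
#' @param width template width parameter (Ricker sigma), seconds.
#' @param rate_jitter fractional jitter on each interval (uniform).
#' @return an object of class `ecg_spec`.
#' @export
ecg_spec <- function(rate = 3.5, amplitude = 3e-5, width = 7e-4,
                     rate_jitter = 0.1) {
  stopifnot(rate > 0, amplitude >= 0, width > 0,
            rate_jitter >= 0, rate_jitter < 1)
  structure(as.list(environment()), class = "ecg_spec")
}

#' Synthetic session configuration
#'
#' Defines a complete simulated recording session: an irregular ~8 Hz
#' click train over `level_grid`, and a three-source voltage model
#' (left ear L, right ear R, vertex V) from which the recorded channels
#' are formed as LV = L - V, RV = R - V, LR = L - R (so LR = LV - RV
#' exactly unless per-channel instrumentation noise is enabled).
#'
#' Each source carries independent 1/f background noise calibrated so
#' every recorded channel has `abr_band_noise_rms` rms within the
#' 300-3000 Hz analysis band, plus shared ECG and breathing artifacts and
#' the level-dependent ABR wavelet. The speaker channel carries the click
#' pulses (volts = `speaker_gain` x pressure).
#'
#' Click intervals are exponential, truncated to
#' `[min_interval, min_interval + max_extra]`, giving a mean interval of
#' ~125 ms (~8 Hz). Each component draws from its own RNG substream so
#' disabling one component does not perturb the others.
#'
#' @param seed master seed; fully determines the session.
#' @param duration seconds.
#' @param sampling_rate Hz.
#' @param level_grid tested click levels, dB SPL.
#' @param min_interval,max_extra,interval_scale truncated-exponential
#'   click-interval parameters, seconds.
#' @param abr an [abr_kernel_spec()].
#' @param ecg an [ecg_spec()].
#' @param breathing_amplitude raw breathing-artifact amplitude, volts.
#' @param breathing_rate Hz.
#' @param abr_band_noise_rms per-channel rms in the 300-3000 Hz band, volts.
#' @param line_noise_amplitude mains interference amplitude, volts
#'   (0 disables).
#' @param line_frequency mains frequency, Hz.
#' @param stimulus_artifact_gain electrical stimulus artifact amplitude at
#'   the loudest level, volts; its sign follows click polarity
#'   (0 disables).
#' @param channel_noise_rms independent white instrumentation noise per
#'   recorded channel, volts rms (0 keeps LR = LV - RV exact).
#' @param speaker_gain speaker channel gain, volts per pascal.
#' @param speaker_side "L" or "R" (metadata only).
#' @param subject,session,recording identifier strings.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 1, duration = 60, sampling_rate = 16000,
                         level_grid = seq(25, 73, by = 4),
                         min_interval = 0.08, max_extra = 0.12,
                         interval_scale = 0.08,
                         abr = abr_kernel_spec(), ecg = ecg_spec(),
                         breathing_amplitude = 1e-4, breathing_rate = 1,
                         abr_band_noise_rms = 1.5e-6,
                         line_noise_amplitude = 0, line_frequency = 50,
                         stimulus_artifact_gain = 0,
                         channel_noise_rms = 0,
                         speaker_gain = 0.01, speaker_side = "L",
                         subject = "sim", session = "s1", recording = "r1") {
  stopifnot(duration > 0, sampling_rate > 0, length(level_grid) >= 1,
            min_interval > 0, max_extra > 0, interval_scale > 0,
            abr_band_noise_rms > 0, speaker_gain > 0,
            inherits(abr, "abr_kernel_spec"), inherits(ecg, "ecg_spec"))
  structure(as.list(environment()), class = "synth_config")
}

# Unit-amplitude wavelet evaluated at times t (seconds after click onset)
# for a given level; most negative extremum at the level's latency.
abr_kernel <- function(t, spec, level, top_level) {
  t0 <- spec$primary_peak_latency +
    spec$latency_slope * (top_level - level)
  -exp(-(t - t0)^2 / (2 * spec$envelope_sigma^2)) *
    cos(2 * pi * (t - t0) / spec$oscillation_period)
}

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

# Target scalar strength (volts) of the noiseless response at `level`.
kernel_strength_target <- function(spec, level, top_level) {
  w <- spec$softplus_width_db
  spec$amplitude_scale * spec$top_strength *
    softplus((level - spec$true_threshold_db) / w) /
    softplus((top_level - spec$true_threshold_db) / w)
}

# Scalar strength of the unit-amplitude wavelet: rolling 1.25 ms SD of the
# kernel on the epoch grid, read at t = +2 ms. Used to convert strength
# targets into wavelet amplitudes.
unit_kernel_strength <- function(spec, sampling_rate,
                                 strength_window = 1.25e-3,
                                 scalar_time = 2e-3) {
  pre <- round(0.0025 * sampling_rate)
  post <- round(0.0075 * sampling_rate)
  t <- (seq_len(pre + post) - pre - 1) / sampling_rate
  g <- abr_kernel(t, spec, level = 0, top_level = 0)
  g[t < 0] <- 0
  s <- rolling_sd(g, round(strength_window * sampling_rate))
  s[which.min(abs(t - scalar_time))]
}

# Ricker (Mexican hat) ECG template on a +/-5 sigma grid.
ecg_template <- function(spec, sampling_rate) {
  t <- seq(-5 * spec$width, 5 * spec$width, by = 1 / sampling_rate)
  (1 - (t / spec$width)^2) * exp(-t^2 / (2 * spec$width^2))
}

# Truncated-exponential click intervals via inverse CDF.
sample_click_intervals <- function(n, config) {
  u <- stats::runif(n)
  s <- config$interval_scale
  config$min_interval - s * log(1 - u * (1 - exp(-config$max_extra / s)))
}

#' Generate a complete synthetic session
#'
#' Produces a raw multi-channel recording (LV, RV, LR, speaker), the
#' stimulus train that was played, and a ground-truth manifest
#' (click onsets/polarities/levels, heartbeat times, wavelet parameters,
#' true threshold). The output is deterministic in `config$seed` and is
#' quantized to the float32 storage precision, so a disk round trip via
#' [write_recording()] is bit-exact.
#'
#' @param config a [synth_config()].
#' @return an object of class `abr_session`: a list with elements
#'   `recording` ([abr_recording()]), `stimulus` (data.frame), and
#'   `manifest` (ground truth list).
#' @examples
#' s <- generate_session(synth_config(seed = 1, duration = 5,
#'                                    level_grid = 73))
#' s$recording
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  top_level <- max(config$level_grid)

  set.seed(config$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 7L)
  # substreams: 1 clicks, 2-4 backgrounds L/R/V, 5 ecg, 6 breathing,
  # 7 channel noise

  ## click train -------------------------------------------------------
  set.seed(sub[1])
  t_end <- config$duration - 0.05
  n_guess <- ceiling(t_end / config$min_interval) + 10
  iv <- sample_click_intervals(n_guess, config)
  times <- 0.1 + cumsum(iv)
  times <- times[times < t_end]
  n_clicks <- length(times)
  if (n_clicks < length(config$level_grid)) {
    stop("duration ", config$duration, " s is too short for at least one ",
         "click per level (", n_clicks, " clicks, ",
         length(config$level_grid), " levels)")
  }
  levels <- config$level_grid[sample.int(length(config$level_grid),
                                         n_clicks, replace = TRUE)]
  if (!all(config$level_grid %in% levels)) {
    stop("duration ", config$duration, " s left some levels without ",
         "clicks; increase duration")
  }
  polarity <- sample(c(-1L, 1L), n_clicks, replace = TRUE)
  onset <- as.integer(round(times * fs)) + 1L

  ## background sources -------------------------------------------------
  # Each channel is a difference of two independent sources, so per-source
  # in-band rms = target / sqrt(2) gives every channel the target rms.
  src_target <- config$abr_band_noise_rms / sqrt(2)
  background <- function(seed) {
    set.seed(seed)
    x <- pink_noise(n, fs)
    x * (src_target / rms(band_filter(x, fs, 300, 3000)))
  }
  VL <- background(sub[2])
  VR <- background(sub[3])
  VV <- background(sub[4])

  ## ECG -----------------------------------------------------------------
  beat_times <- numeric(0)
  if (config$ecg$amplitude > 0) {
    set.seed(sub[5])
    nb_guess <- ceiling(config$duration * config$ecg$rate) + 10
    biv <- (1 / config$ecg$rate) *
      (1 + config$ecg$rate_jitter * stats::runif(nb_guess, -1, 1))
    beat_times <- 0.2 + cumsum(biv)
    beat_times <- beat_times[beat_times < config$duration - 0.2]
    tpl <- ecg_template(config$ecg, fs)
    # calibrate: ABR-band peak on the most affected channel (LV, source
    # gain contrast 0.8) equals the configured amplitude
    pad <- numeric(max(4096, length(tpl) * 4))
    pad[seq_along(tpl) + 1024] <- tpl
    band_peak <- max(abs(band_filter(pad, fs, 300, 3000)))
    ecg_gain <- c(L = 1, R = 0.7, V = 0.2)
    amp <- config$ecg$amplitude / ((ecg_gain["L"] - ecg_gain["V"]) * band_peak)
    half <- (length(tpl) - 1L) %/% 2L
    for (bt in beat_times) {
      i0 <- round(bt * fs) + 1L - half
      idx <- i0:(i0 + length(tpl) - 1L)
      keep <- idx >= 1L & idx <= n
      w <- tpl[keep] * amp
      VL[idx[keep]] <- VL[idx[keep]] + ecg_gain["L"] * w
      VR[idx[keep]] <- VR[idx[keep]] + ecg_gain["R"] * w
      VV[idx[keep]] <- VV[idx[keep]] + ecg_gain["V"] * w
    }
  }

  ## breathing ----------------------------------------------------------
  if (config$breathing_amplitude > 0) {
    set.seed(sub[6])
    tt <- (seq_len(n) - 1) / fs
    phase <- stats::runif(1, 0, 2 * pi)
    breath_gain <- c(L = 1, R = 0.9, V = 0.3)
    # raw amplitude on LV (gain contrast 0.7) equals the configured value
    b <- (config$breathing_amplitude / 0.7) *
      sin(2 * pi * config$breathing_rate * tt + phase)
    VL <- VL + breath_gain["L"] * b
    VR <- VR + breath_gain["R"] * b
    VV <- VV + breath_gain["V"] * b
  }

  ## mains interference -------------------------------------------------
  if (config$line_noise_amplitude > 0) {
    tt <- (seq_len(n) - 1) / fs
    l <- config$line_noise_amplitude * sin(2 * pi * config$line_frequency * tt)
    VL <- VL + l
    VR <- VR + 0.95 * l
    VV <- VV + 0.90 * l
  }

  ## evoked responses ---------------------------------------------------
  spec <- config$abr
  klen <- round(0.006 * fs)
  tseg <- (seq_len(klen) - 1) / fs
  if (spec$amplitude_scale > 0 && spec$top_strength > 0) {
    r <- unit_kernel_strength(spec, fs)
    kernels_L <- lapply(config$level_grid, function(lv) {
      (kernel_strength_target(spec, lv, top_level) / r) *
        abr_kernel(tseg, spec, lv, top_level)
    })
    kernels_R <- lapply(config$level_grid, function(lv) {
      spec$right_gain *
        (kernel_strength_target(spec, lv, top_level) / r) *
        abr_kernel(tseg - spec$interaural_delay, spec, lv, top_level)
    })
    names(kernels_L) <- names(kernels_R) <- as.character(config$level_grid)
    for (k in seq_len(n_clicks)) {
      idx <- onset[k]:(onset[k] + klen - 1L)
      if (idx[klen] > n) next
      lv <- as.character(levels[k])
      VL[idx] <- VL[idx] + kernels_L[[lv]]
      VR[idx] <- VR[idx] + kernels_R[[lv]]
    }
  }

  ## electrical stimulus artifact ---------------------------------------
  if (config$stimulus_artifact_gain > 0) {
    art_gain <- c(L = 1, R = 0.5, V = 0)
    a <- config$stimulus_artifact_gain * polarity *
      10^((levels - top_level) / 20)
    VL[onset] <- VL[onset] + art_gain["L"] * a
    VR[onset] <- VR[onset] + art_gain["R"] * a
  }

  ## recorded channels --------------------------------------------------
  LV <- VL - VV
  RV <- VR - VV
  LR <- VL - VR
  if (config$channel_noise_rms > 0) {
    set.seed(sub[7])
    LV <- LV + stats::rnorm(n, sd = config$channel_noise_rms)
    RV <- RV + stats::rnorm(n, sd = config$channel_noise_rms)
    LR <- LR + stats::rnorm(n, sd = config$channel_noise_rms)
  }
  speaker <- numeric(n)
  speaker[onset] <- polarity * click_pressure_pa(levels) * config$speaker_gain

  samples <- cbind(LV = float32(LV), RV = float32(RV), LR = float32(LR),
                   speaker = float32(speaker))
  recording <- abr_recording(
    samples, fs,
    metadata = list(subject = config$subject, session = config$session,
                    recording = config$recording,
                    speaker_side = config$speaker_side,
                    synthetic = TRUE, seed = config$seed))

  stimulus <- data.frame(onset_sample = onset,
                         onset_time_s = (onset - 1) / fs,
                         polarity = polarity,
                         nominal_level_db = levels)

  manifest <- list(
    seed = config$seed,
    clicks = stimulus,
    beat_times = beat_times,
    true_threshold_db = spec$true_threshold_db,
    kernel = spec,
    ecg = config$ecg,
    abr_band_noise_rms = config$abr_band_noise_rms,
    outlier_trials = integer(0))

  structure(list(recording = recording, stimulus = stimulus,
                 manifest = manifest, config = config),
            class = "abr_session")
}

#' @export
print.abr_session <- function(x, ...) {
  cat("<abr_session> seed ", x$manifest$seed, ", ",
      nrow(x$stimulus), " clicks over ",
      length(unique(x$stimulus$nominal_level_db)), " level(s)\n", sep = "")
  print(x$recording)
  invisible(x)
}

#' Inject gross outlier trials into a session
#'
#' Multiplies the electrode-channel samples of `n_outliers` randomly
#' chosen trial epochs by `scale`, emulating movement or ECG artifacts
#' large enough to trip the 3-SD rejection criteria, and records the
#' affected trial indices in the manifest.
#'
#' @param session an `abr_session` from [generate_session()].
#' @param n_outliers number of trials to corrupt.
#' @param scale multiplicative factor (values <= 1 warn: such trials may
#'   not exceed the rejection criteria).
#' @param seed RNG seed for choosing trials (defaults to a fixed offset of
#'   the session seed).
#' @param epoch_window epoch extent in seconds relative to click onset.
#' @return the modified `abr_session` with `manifest$outlier_trials` set.
#' @export
inject_outlier_trials <- function(session, n_outliers, scale = 10,
                                  seed = session$manifest$seed + 7919,
                                  epoch_window = c(-0.0025, 0.0075)) {
  stopifnot(inherits(session, "abr_session"))
  n_trials <- nrow(session$stimulus)
  if (n_outliers > n_trials) {
    stop("n_outliers (", n_outliers, ") exceeds trial count (", n_trials, ")")
  }
  if (n_outliers == 0) return(session)
  if (scale <= 1) {
    warning("scale <= 1 may not push trials over the rejection criteria")
  }
  fs <- session$recording$sampling_rate
  set.seed(seed)
  picked <- sort(sample.int(n_trials, n_outliers))
  pre <- round(-epoch_window[1] * fs)
  post <- round(epoch_window[2] * fs)
  chans <- electrode_channels(session$recording)
  len <- n_samples(session$recording)
  for (tr in picked) {
    o <- session$stimulus$onset_sample[tr]
    idx <- max(1L, o - pre):min(len, o + post - 1L)
    session$recording$samples[idx, chans] <-
      float32(session$recording$samples[idx, chans] * scale)
  }
  session$manifest$outlier_trials <- picked
  session
}
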