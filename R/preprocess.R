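#' Signal-processing pipeline configuration
#'
#' Parameters of the standard ABR pipeline: zero-phase 2nd-order
#' Butterworth filtering into the 300-3000 Hz "ABR band" (20-500 Hz for
#' ECG inspection, 0.1 Hz highpass for raw display), epoching from 2.5 ms
#' before to 7.5 ms after each click, and 3-SD outlier-trial rejection.
#'
#' @param abr_band length-2 Hz vector, the analysis band.
#' @param ecg_band length-2 Hz vector, the ECG band.
#' @param display_highpass Hz, highpass for raw-trace display.
#' @param filter_order Butterworth design order.
#' @param epoch_window length-2 seconds relative to click onset
#'   (must contain 0).
#' @param rejection_sigmas SD multiple for outlier-trial rejection.
#' @param rejection_center `"mean"` (default) or `"median"`: the location
#'   statistic defining the "typical" trial.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(abr_band = c(300, 3000),
                            ecg_band = c(20, 500),
                            display_highpass = 0.1,
                            filter_order = 2,
                            epoch_window = c(-0.0025, 0.0075),
                            rejection_sigmas = 3,
                            rejection_center = c("mean", "median")) {
  rejection_center <- match.arg(rejection_center)
  stopifnot(length(abr_band) == 2, abr_band[1] > 0, abr_band[1] < abr_band[2],
            length(ecg_band) == 2, ecg_band[1] > 0, ecg_band[1] < ecg_band[2],
            display_highpass > 0, filter_order >= 1,
            length(epoch_window) == 2, epoch_window[1] < 0,
            epoch_window[2] > 0, rejection_sigmas > 0)
  structure(
    list(abr_band = abr_band, ecg_band = ecg_band,
         display_highpass = display_highpass,
         filter_order = as.integer(filter_order),
         epoch_window = epoch_window,
         rejection_sigmas = rejection_sigmas,
         rejection_center = rejection_center),
    class = "pipeline_config")
}

#' Zero-phase Butterworth filtering of a recording
#'
#' Applies a 2nd-order (by design; the bandpass realization has twice the
#' coefficients) Butterworth filter forward and backward, so the filter is
#' zero-phase and peak latencies are not shifted. The forward-backward
#' pass doubles the effective attenuation. The speaker channel is left
#' untouched by default.
#'
#' @param recording an [abr_recording()].
#' @param low,high band edges in Hz (must lie below Nyquist).
#' @param order Butterworth design order.
#' @param channels channels to filter (default: all electrode channels).
#' @return the filtered [abr_recording()].
#' @export
bandpass_filter <- function(recording, low = 300, high = 3000, order = 2,
                            channels = electrode_channels(recording)) {
  for (ch in channels) {
    recording$samples[, ch] <-
      band_filter(recording$samples[, ch], recording$sampling_rate,
                  low, high, order)
  }
  recording$metadata$band <- c(low, high)
  recording
}

#' @rdname bandpass_filter
#' @param cutoff highpass cutoff in Hz.
#' @export
highpass_filter <- function(recording, cutoff = 0.1, order = 2,
                            channels = electrode_channels(recording)) {
  for (ch in channels) {
    recording$samples[, ch] <-
      high_filter(recording$samples[, ch], recording$sampling_rate,
                  cutoff, order)
  }
  recording
}

#' Detect heartbeats (ECG) in a recording
#'
#' The ECG rides on the electrode channels as large (~30 uV) spikes at
#' 3-4 Hz. Beats are detected on the 20-500 Hz band by thresholding at
#' `threshold_sigmas` robust SDs with a refractory interval, and a mean
#' beat-aligned template is extracted. The default of six SDs keeps the
#' expected number of chance crossings in a multi-minute Gaussian-noise
#' recording well below one, while beats exceed the in-band background
#' roughly twenty-fold. A heart rate outside
#' `plausible_rate` triggers a warning (useful as an anesthesia/electrode
#' check), not an error.
#'
#' @param recording an [abr_recording()] (raw, unfiltered).
#' @param config a [pipeline_config()] (supplies the ECG band and filter
#'   order).
#' @param channel channel to detect on.
#' @param threshold_sigmas detection threshold in robust SDs.
#' @param refractory minimum beat separation, seconds.
#' @param template_window half-width of the beat-aligned template, seconds.
#' @param plausible_rate length-2 Hz range; rates outside it warn.
#' @return an object of class `ecg_summary`: beat sample indices, heart
#'   rate in Hz (`(n_beats - 1) / span`), the aligned template, and the
#'   channel used. Zero beats yield an empty summary with a warning.
#' @export
detect_ecg <- function(recording, config = pipeline_config(),
                       channel = "LV", threshold_sigmas = 6,
                       refractory = 0.15, template_window = 0.02,
                       plausible_rate = c(2, 8)) {
  fs <- recording$sampling_rate
  x <- band_filter(channel(recording, channel), fs,
                   config$ecg_band[1], config$ecg_band[2],
                   config$filter_order)
  sigma <- stats::mad(x)
  thr <- threshold_sigmas * sigma
  idx <- which(abs(x) > thr)
  # zero-phase IIR filtering leaves transients at the series edges; ignore
  # events within one period of the band's low edge of either end
  guard <- round(fs / config$ecg_band[1])
  idx <- idx[idx > guard & idx <= length(x) - guard]
  empty <- structure(list(beats = integer(0), heart_rate = NA_real_,
                          template = numeric(0), template_time = numeric(0),
                          channel = channel, sampling_rate = fs),
                     class = "ecg_summary")
  if (!length(idx)) {
    warning("no heartbeats detected on channel ", channel)
    return(empty)
  }
  refr <- round(refractory * fs)
  starts <- idx[c(TRUE, diff(idx) > refr)]
  # align each event to its absolute peak
  beats <- vapply(starts, function(s) {
    win <- s:min(length(x), s + refr)
    win[which.max(abs(x[win]))]
  }, integer(1))
  heart_rate <- if (length(beats) >= 2) {
    (length(beats) - 1) / ((beats[length(beats)] - beats[1]) / fs)
  } else NA_real_
  if (!is.na(heart_rate) &&
      (heart_rate < plausible_rate[1] || heart_rate > plausible_rate[2])) {
    warning(sprintf("heart rate %.2f Hz outside the plausible range [%g, %g]",
                    heart_rate, plausible_rate[1], plausible_rate[2]))
  }
  hw <- round(template_window * fs)
  full <- beats[beats - hw >= 1 & beats + hw <= length(x)]
  template <- if (length(full)) {
    rowMeans(vapply(full, function(b) x[(b - hw):(b + hw)],
                    numeric(2 * hw + 1)))
  } else numeric(0)
  structure(list(beats = beats, heart_rate = heart_rate,
                 template = template,
                 template_time = if (length(template))
                   ((-hw):hw) / fs else numeric(0),
                 channel = channel, sampling_rate = fs),
            class = "ecg_summary")
}

#' @export
print.ecg_summary <- function(x, ...) {
  cat("<ecg_summary> ", length(x$beats), " beats on ", x$channel,
      if (!is.na(x$heart_rate))
        sprintf(", heart rate %.2f Hz", x$heart_rate) else "",
      "\n", sep = "")
  invisible(x)
}

#' Epoch a recording into trials
#'
#' Cuts the electrode channels into one epoch per click, spanning
#' `epoch_window` (default 2.5 ms before to 7.5 ms after onset; 160
#' samples at 16 kHz, 40 pre + 120 post). The window is half-open in
#' samples: `[onset - round(pre * fs), onset + round(post * fs))`.
#' Clicks whose full window does not fit inside the recording are
#' dropped (counted in `n_clipped`).
#'
#' @param recording a band-filtered [abr_recording()].
#' @param stimulus stimulus data.frame with `onset_sample`, `polarity`,
#'   `nominal_level_db`.
#' @param config a [pipeline_config()].
#' @param channels channels to epoch (default: electrode channels).
#' @return an object of class `trial_tensor`: `epochs` (trials x time x
#'   channels array), `labels` (per-trial data.frame), `include` (logical
#'   inclusion mask), `time` (seconds relative to onset), `n_clipped`,
#'   `sampling_rate`, `metadata`.
#' @export
epoch_trials <- function(recording, stimulus, config = pipeline_config(),
                         channels = electrode_channels(recording)) {
  fs <- recording$sampling_rate
  pre <- round(-config$epoch_window[1] * fs)
  post <- round(config$epoch_window[2] * fs)
  len <- pre + post
  nsamp <- n_samples(recording)
  ok <- stimulus$onset_sample - pre >= 1 &
    stimulus$onset_sample + post - 1 <= nsamp
  n_clipped <- sum(!ok)
  keep <- stimulus[ok, , drop = FALSE]
  if (!nrow(keep)) {
    stop("no complete trials: all ", nrow(stimulus),
         " click windows fall outside the recording")
  }
  epochs <- array(NA_real_,
                  dim = c(nrow(keep), len, length(channels)),
                  dimnames = list(NULL, NULL, channels))
  for (ci in seq_along(channels)) {
    x <- recording$samples[, channels[ci]]
    offs <- as.integer(outer(keep$onset_sample - pre,
                             0:(len - 1L), `+`))
    epochs[, , ci] <- x[offs]
  }
  structure(
    list(epochs = epochs,
         labels = data.frame(level = keep$nominal_level_db,
                             polarity = keep$polarity,
                             onset_sample = keep$onset_sample),
         include = rep(TRUE, nrow(keep)),
         time = (seq_len(len) - pre - 1) / fs,
         n_clipped = n_clipped,
         sampling_rate = fs,
         metadata = recording$metadata),
    class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  cat("<trial_tensor> ", dim(x$epochs)[1], " trials x ", dim(x$epochs)[2],
      " samples x ", dim(x$epochs)[3], " channel(s); ",
      sum(x$include), " included", sep = "")
  if (x$n_clipped) cat(", ", x$n_clipped, " clipped at edges", sep = "")
  cat("\n")
  invisible(x)
}

#' Reject outlier trials
#'
#' For each channel, computes two per-trial statistics over the full
#' epoch -- the maximum absolute value and the rms -- and drops any trial
#' for which either statistic exceeds the typical trial (mean, or median
#' via `config$rejection_center`) by at least `rejection_sigmas` standard
#' deviations. Statistics are computed in a single pass over all trials
#' of the recording; a trial rejected on any channel is rejected for all
#' channels (the artifact is shared physiology). Trials already excluded
#' stay excluded.
#'
#' @param tensor a [epoch_trials()] result (>= 3 trials).
#' @param config a [pipeline_config()].
#' @param combine `"any"` (default): a trial flagged on any channel is
#'   dropped everywhere; `"per_channel"` is intentionally not offered --
#'   the mask is shared.
#' @return the tensor with an updated `include` mask and a `rejection`
#'   attribute: a data.frame of flagged (trial, channel, statistic, value,
#'   threshold) rows.
#' @export
reject_outliers <- function(tensor, config = pipeline_config(),
                            combine = "any") {
  stopifnot(inherits(tensor, "trial_tensor"))
  n_trials <- dim(tensor$epochs)[1]
  if (n_trials < 3) stop("outlier rejection needs at least 3 trials")
  center <- switch(config$rejection_center,
                   mean = mean, median = stats::median)
  chans <- dimnames(tensor$epochs)[[3]]
  report <- list()
  flagged <- rep(FALSE, n_trials)
  for (ch in chans) {
    e <- tensor$epochs[, , ch]
    stat <- list(max_abs = apply(abs(e), 1, max),
                 rms = sqrt(rowMeans(e^2)))
    for (sn in names(stat)) {
      s <- stat[[sn]]
      thr <- center(s) + config$rejection_sigmas * stats::sd(s)
      hit <- s > thr
      if (any(hit)) {
        report[[length(report) + 1L]] <- data.frame(
          trial = which(hit), channel = ch, statistic = sn,
          value = s[hit], threshold = thr)
      }
      flagged <- flagged | hit
    }
  }
  include <- tensor$include & !flagged
  if (!any(include)) {
    stop("all trials rejected in recording '",
         tensor$metadata$recording %||% "?", "'")
  }
  tensor$include <- include
  attr(tensor, "rejection") <- if (length(report)) {
    do.call(rbind, report)
  } else {
    data.frame(trial = integer(0), channel = character(0),
               statistic = character(0), value = numeric(0),
               threshold = numeric(0))
  }
  tensor
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average trials by sound level
#'
#' Arithmetic mean of the included trials of each (channel, level) cell,
#' with the baseline rms of the averaged waveform computed over
#' `baseline_window` (default -2.5 to -1.25 ms). When both click
#' polarities are present in a cell the pooled mean is the unweighted
#' mean of the two per-polarity means (`balanced = TRUE`), so any
#' polarity-flipping electrical stimulus artifact cancels exactly even if
#' the polarity counts are unequal. Per-polarity means are returned when
#' `by_polarity = TRUE`.
#'
#' @param tensor a [trial_tensor] (inclusion mask already applied).
#' @param by_polarity also return per-polarity means.
#' @param balanced balance polarities in the pooled mean (see above).
#' @param baseline_window length-2 seconds (half-open) for the baseline
#'   rms.
#' @return an object of class `averaged_abr`: `mean` (levels x time x
#'   channels array), `n_trials` (per level), `baseline_rms` (levels x
#'   channels), `levels`, `time`, `sampling_rate`, and optionally
#'   `polarity` (levels x time x channels x c("-1","+1")).
#' @export
average_by_level <- function(tensor, by_polarity = FALSE, balanced = TRUE,
                             baseline_window = c(-0.0025, -0.00125)) {
  stopifnot(inherits(tensor, "trial_tensor"))
  inc <- which(tensor$include)
  if (!length(inc)) stop("no included trials to average")
  all_levels <- sort(unique(tensor$labels$level))
  levels <- sort(unique(tensor$labels$level[inc]))
  if (length(dropped <- setdiff(all_levels, levels))) {
    warning("level(s) with no included trials omitted: ",
            paste(dropped, collapse = ", "))
  }
  chans <- dimnames(tensor$epochs)[[3]]
  nt <- length(tensor$time)
  avg <- array(NA_real_, dim = c(length(levels), nt, length(chans)),
               dimnames = list(as.character(levels), NULL, chans))
  pol_avg <- if (by_polarity) {
    array(NA_real_, dim = c(length(levels), nt, length(chans), 2),
          dimnames = list(as.character(levels), NULL, chans, c("-1", "1")))
  } else NULL
  n_trials <- integer(length(levels))
  for (li in seq_along(levels)) {
    rows <- inc[tensor$labels$level[inc] == levels[li]]
    n_trials[li] <- length(rows)
    pols <- tensor$labels$polarity[rows]
    for (ci in seq_along(chans)) {
      e <- tensor$epochs[rows, , ci, drop = FALSE]
      dim(e) <- c(length(rows), nt)
      m_neg <- if (any(pols < 0)) colMeans(e[pols < 0, , drop = FALSE])
      m_pos <- if (any(pols > 0)) colMeans(e[pols > 0, , drop = FALSE])
      avg[li, , ci] <- if (balanced && !is.null(m_neg) && !is.null(m_pos)) {
        (m_neg + m_pos) / 2
      } else {
        colMeans(e)
      }
      if (by_polarity) {
        if (!is.null(m_neg)) pol_avg[li, , ci, "-1"] <- m_neg
        if (!is.null(m_pos)) pol_avg[li, , ci, "1"] <- m_pos
      }
    }
  }
  bidx <- tensor$time >= baseline_window[1] & tensor$time < baseline_window[2]
  baseline_rms <- matrix(NA_real_, length(levels), length(chans),
                         dimnames = list(as.character(levels), chans))
  for (li in seq_along(levels)) {
    for (ci in seq_along(chans)) {
      baseline_rms[li, ci] <- rms(avg[li, bidx, ci])
    }
  }
  structure(
    list(mean = avg, n_trials = n_trials, baseline_rms = baseline_rms,
         levels = levels, time = tensor$time,
         sampling_rate = tensor$sampling_rate,
         polarity = pol_avg, metadata = tensor$metadata),
    class = "averaged_abr")
}

#' @export
print.averaged_abr <- function(x, ...) {
  cat("<averaged_abr> ", length(x$levels), " level(s) x ",
      length(x$time), " samples x ", dim(x$mean)[3], " channel(s); ",
      sum(x$n_trials), " trials\n", sep = "")
  cat(sprintf("  levels %g..%g dB SPL, baseline rms %.3g..%.3g uV\n",
              min(x$levels), max(x$levels),
              min(x$baseline_rms, na.rm = TRUE) * 1e6,
              max(x$baseline_rms, na.rm = TRUE) * 1e6))
  invisible(x)
}

#' @export
plot.averaged_abr <- function(x, channel = dimnames(x$mean)[[3]][1],
                              ...) {
  pal <- grDevices::hcl.colors(length(x$levels), "viridis")
  m <- x$mean[, , channel, drop = FALSE] * 1e6
  graphics::matplot(x$time * 1e3, t(m[, , 1]), type = "l", lty = 1,
                    col = pal, xlab = "time re click (ms)",
                    ylab = expression(mu * V),
                    main = paste("ABR,", channel), ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
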