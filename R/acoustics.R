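#' Acoustic calibration configuration
#'
#' Constants used to express click stimuli in dB SPL and to reason about
#' propagation delays. The click is a single-sample pulse whose acoustic
#' energy is concentrated in about 0.5 ms, but perceived loudness
#' integrates over roughly 50 ms, so the reported level divides the peak
#' pressure excursion by `integration_window / effective_click_duration`
#' (= 100) before referring it to 20 uPa.
#'
#' @param reference_pressure reference pressure in Pa (20 uPa).
#' @param speed_of_sound in m/s (343 at 20 degrees C).
#' @param integration_window loudness integration window, seconds.
#' @param effective_click_duration effective click duration, seconds.
#' @param level_grid tested click levels in dB SPL (uniform 4 dB steps).
#' @return an object of class `acoustics_config`.
#' @export
acoustics_config <- function(reference_pressure = 2e-5,
                             speed_of_sound = 343,
                             integration_window = 0.050,
                             effective_click_duration = 0.0005,
                             level_grid = seq(25, 73, by = 4)) {
  stopifnot(reference_pressure > 0, speed_of_sound > 0,
            integration_window > 0, effective_click_duration > 0,
            length(level_grid) >= 2)
  if (any(diff(level_grid) <= 0) ||
      length(unique(round(diff(level_grid), 9))) != 1) {
    stop("level_grid must be strictly increasing with a uniform step")
  }
  structure(
    list(reference_pressure = reference_pressure,
         speed_of_sound = speed_of_sound,
         integration_window = integration_window,
         effective_click_duration = effective_click_duration,
         level_grid = level_grid),
    class = "acoustics_config")
}

#' Speaker placement geometry
#'
#' @param lateral_offset speaker distance lateral to the nearest ear, m.
#' @param dorsal_offset speaker distance dorsal to the nearest ear, m.
#' @param interaural_distance distance between the two ears, m.
#' @return an object of class `speaker_geometry`.
#' @export
speaker_geometry <- function(lateral_offset = 0.13,
                             dorsal_offset = 0.03,
                             interaural_distance = 0.01) {
  stopifnot(lateral_offset >= 0, dorsal_offset >= 0,
            interaural_distance >= 0)
  structure(
    list(lateral_offset = lateral_offset, dorsal_offset = dorsal_offset,
         interaural_distance = interaural_distance),
    class = "speaker_geometry")
}

#' @rdname speaker_geometry
#' @param geometry a [speaker_geometry()].
#' @export
speaker_distance <- function(geometry = speaker_geometry()) {
  sqrt(geometry$lateral_offset^2 + geometry$dorsal_offset^2)
}

#' Click sound level in dB SPL
#'
#' For a brief click the maximum peak-to-peak pressure is divided by
#' `integration_window / effective_click_duration` (default 100) and
#' referred to 20 uPa: `20 * log10((pp / 100) / p_ref)`. The alternative
#' `mode = "rms"` refers the rms pressure over the integration window to
#' the same reference and gives similar values for these stimuli.
#'
#' @param pressure_waveform pressure time series in Pa covering the click.
#' @param config an [acoustics_config()].
#' @param mode `"peak_to_peak"` (default) or `"rms"`.
#' @return level in dB SPL.
#' @examples
#' click_level_dbspl(c(0, 2e-3, 0))   # peak-to-peak 2 mPa -> 0 dB SPL
#' @export
click_level_dbspl <- function(pressure_waveform, config = acoustics_config(),
                              mode = c("peak_to_peak", "rms")) {
  mode <- match.arg(mode)
  if (length(pressure_waveform) < 2 ||
      diff(range(pressure_waveform)) == 0) {
    stop("cannot define a click level for a constant waveform")
  }
  p <- switch(mode,
    peak_to_peak = diff(range(pressure_waveform)) /
      (config$integration_window / config$effective_click_duration),
    rms = rms(pressure_waveform))
  20 * log10(p / config$reference_pressure)
}

# Peak-to-peak pressure (Pa) that a single-sample click needs to be
# reported at `level` dB SPL; exact inverse of click_level_dbspl().
click_pressure_pa <- function(level, config = acoustics_config()) {
  (config$integration_window / config$effective_click_duration) *
    config$reference_pressure * 10^(level / 20)
}

#' Acoustic propagation delay
#'
#' Time for sound to travel `distance` meters: `distance / speed_of_sound`
#' (about 0.4 ms for the standard speaker placement, 0.03 ms across the
#' ears). Stimulus time zero is defined at speaker onset, i.e. analyses do
#' not subtract this delay; the function exists to reason about latencies.
#'
#' @param distance in meters (>= 0).
#' @param config an [acoustics_config()].
#' @return delay in seconds.
#' @export
propagation_delay <- function(distance, config = acoustics_config()) {
  if (any(distance < 0)) stop("distance must be nonnegative")
  distance / config$speed_of_sound
}

#' Detect click onsets on the speaker channel
#'
#' Threshold detector for the recorded speaker voltage: events are samples
#' whose magnitude exceeds `threshold_sigmas` robust standard deviations
#' (MAD) of the channel, merged within a refractory interval shorter than
#' the minimum inter-click spacing. Each event's onset is refined to the
#' first sample reaching `onset_fraction` of the event peak; polarity is
#' the sign of the first deflection.
#'
#' @param speaker_voltage numeric vector (DC-free speaker channel).
#' @param sampling_rate Hz.
#' @param threshold_sigmas detection threshold in robust SDs.
#' @param refractory minimum event separation, seconds.
#' @param onset_fraction fraction of the event peak defining onset.
#' @param event_window how far past the first crossing to search for the
#'   peak, seconds.
#' @return data.frame with columns `onset_sample`, `onset_time_s`
#'   (sample 1 = time 0), `polarity` (+1/-1). Zero rows, with a warning,
#'   when no suprathreshold events exist.
#' @export
detect_click_onsets <- function(speaker_voltage, sampling_rate,
                                threshold_sigmas = 5, refractory = 0.05,
                                onset_fraction = 0.1, event_window = 0.002) {
  empty <- data.frame(onset_sample = integer(0), onset_time_s = numeric(0),
                      polarity = integer(0))
  peak <- max(abs(speaker_voltage))
  if (peak == 0) {
    warning("speaker channel is constant; no clicks detected")
    return(empty)
  }
  # MAD tracks the channel noise floor; on a digitally silent channel
  # (sparse pulses on exact zeros) it vanishes, so fall back to a fixed
  # fraction of the largest event -- 1/500 spans a > 50 dB stimulus range.
  sigma <- stats::mad(speaker_voltage)
  thr <- max(threshold_sigmas * sigma, peak / 500)
  idx <- which(abs(speaker_voltage) > thr)
  if (!length(idx)) {
    warning("no suprathreshold events on the speaker channel")
    return(empty)
  }
  refr <- round(refractory * sampling_rate)
  starts <- idx[c(TRUE, diff(idx) > refr)]
  ew <- round(event_window * sampling_rate)
  len <- length(speaker_voltage)
  onset <- integer(length(starts))
  pol <- integer(length(starts))
  for (k in seq_along(starts)) {
    win <- max(1L, starts[k] - 3L):min(len, starts[k] + ew)
    seg <- abs(speaker_voltage[win])
    o <- win[which(seg >= onset_fraction * max(seg))[1]]
    onset[k] <- o
    pol[k] <- sign(speaker_voltage[o])
  }
  data.frame(onset_sample = onset,
             onset_time_s = (onset - 1) / sampling_rate,
             polarity = as.integer(pol))
}

#' Estimate click levels from the speaker channel
#'
#' Converts the peak-to-peak speaker voltage around each detected onset to
#' pressure via the speaker gain, then to dB SPL via
#' [click_level_dbspl()].
#'
#' @param stimulus a stimulus data.frame with `onset_sample`.
#' @param speaker_voltage speaker channel, volts.
#' @param speaker_gain speaker/mic chain gain in volts per pascal.
#' @param sampling_rate Hz.
#' @param window seconds around each onset used for the peak-to-peak.
#' @param config an [acoustics_config()].
#' @return the stimulus data.frame with an `estimated_level_db` column.
#' @export
click_levels_from_speaker <- function(stimulus, speaker_voltage, speaker_gain,
                                      sampling_rate, window = 0.002,
                                      config = acoustics_config()) {
  hw <- round(window * sampling_rate)
  len <- length(speaker_voltage)
  stimulus$estimated_level_db <- vapply(stimulus$onset_sample, function(o) {
    seg <- speaker_voltage[max(1, o - 2):min(len, o + hw)] / speaker_gain
    click_level_dbspl(seg, config)
  }, numeric(1))
  stimulus
}

#' Read and write stimulus trains
#'
#' Stimulus trains are plain CSV with columns `onset_sample`,
#' `onset_time_s`, `polarity`, `nominal_level_db`.
#'
#' @param stimulus stimulus data.frame.
#' @param path CSV file path.
#' @return `read_stimulus_csv` returns the data.frame;
#'   `write_stimulus_csv` returns `path` invisibly.
#' @export
write_stimulus_csv <- function(stimulus, path) {
  utils::write.csv(stimulus, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_csv
#' @export
read_stimulus_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("onset_sample", "onset_time_s", "polarity", "nominal_level_db")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("stimulus file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}
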