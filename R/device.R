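#' Acquisition device profile
#'
#' Constants of the 8-channel, 24-bit delta-sigma acquisition front end.
#' At the default reference voltage (4.5 V) and maximum programmable gain
#' (24) the full-scale input is +/-187 mV and one least-significant bit
#' (LSB) is about 22 nV, so the usable dynamic range spans almost seven
#' orders of magnitude. The reference voltage is not printed in the
#' hardware description; 4.5 V is the value that makes the published
#' +/-187 mV / 22 nV pair exact and is the chip's internal reference.
#'
#' Each input carries a passive RC prefilter formed by the electrode
#' impedance and a capacitor to ground; see [prefilter_cutoff()].
#'
#' @param reference_voltage ADC reference in volts.
#' @param gain programmable gain (dimensionless, > 0).
#' @param adc_bits converter resolution in bits (>= 2).
#' @param sampling_rate sampling rate in Hz.
#' @param n_channels number of differential input channels.
#' @param electrode_impedance assumed electrode impedance in ohms.
#' @param prefilter_capacitance input capacitor to ground, in farads.
#' @return an object of class `device_profile`.
#' @examples
#' p <- device_profile()
#' lsb_volts(p) * 1e9   # ~22 nV
#' full_scale_volts(p)  # ~0.1875 V
#' @export
device_profile <- function(reference_voltage = 4.5,
                           gain = 24,
                           adc_bits = 24L,
                           sampling_rate = 16000,
                           n_channels = 8L,
                           electrode_impedance = 1e4,
                           prefilter_capacitance = 4.7e-9) {
  stopifnot(reference_voltage > 0, gain > 0, adc_bits >= 2,
            sampling_rate > 0, n_channels >= 1)
  structure(
    list(reference_voltage = reference_voltage,
         gain = gain,
         adc_bits = as.integer(adc_bits),
         sampling_rate = sampling_rate,
         n_channels = as.integer(n_channels),
         electrode_impedance = electrode_impedance,
         prefilter_capacitance = prefilter_capacitance),
    class = "device_profile")
}

#' @export
print.device_profile <- function(x, ...) {
  cat("<device_profile>\n")
  cat(sprintf("  %d channels @ %g Hz, %d-bit, gain %g\n",
              x$n_channels, x$sampling_rate, x$adc_bits, x$gain))
  cat(sprintf("  full scale +/-%.4g mV, LSB %.4g nV\n",
              full_scale_volts(x) * 1e3, lsb_volts(x) * 1e9))
  cat(sprintf("  RC prefilter: %.3g kOhm x %.3g nF -> %.0f Hz\n",
              x$electrode_impedance / 1e3, x$prefilter_capacitance * 1e9,
              prefilter_cutoff(x)))
  invisible(x)
}

#' Full-scale amplitude and LSB voltage
#'
#' The full-scale amplitude is `reference_voltage / gain` (the input range
#' is +/- this value) and the LSB is `2 * full_scale / 2^adc_bits`.
#'
#' @param profile a [device_profile()].
#' @return voltage in volts.
#' @export
full_scale_volts <- function(profile) {
  profile$reference_voltage / profile$gain
}

#' @rdname full_scale_volts
#' @export
lsb_volts <- function(profile) {
  2 * full_scale_volts(profile) / 2^profile$adc_bits
}

#' Convert ADC codes to volts (and back)
#'
#' Signed integer converter codes map linearly to input-referred volts:
#' `volts = code * lsb`. The map is odd-symmetric and strictly increasing.
#'
#' @param codes integer vector of signed ADC codes.
#' @param volts numeric vector of voltages.
#' @param profile a [device_profile()].
#' @return `codes_to_volts`: numeric voltages; `volts_to_codes`: integer
#'   codes (rounded to the nearest LSB).
#' @examples
#' codes_to_volts(1L, device_profile()) * 1e9  # one LSB ~ 22 nV
#' @export
codes_to_volts <- function(codes, profile = device_profile()) {
  lim <- 2^(profile$adc_bits - 1)
  if (any(codes < -lim | codes > lim - 1)) {
    stop("ADC code out of the signed ", profile$adc_bits, "-bit range [",
         -lim, ", ", lim - 1, "]")
  }
  as.numeric(codes) * lsb_volts(profile)
}

#' @rdname codes_to_volts
#' @export
volts_to_codes <- function(volts, profile = device_profile()) {
  codes <- round(volts / lsb_volts(profile))
  lim <- 2^(profile$adc_bits - 1)
  if (any(codes < -lim | codes > lim - 1)) {
    stop("voltage exceeds the +/-", signif(full_scale_volts(profile), 4),
         " V input range")
  }
  as.integer(codes)
}

#' Analog prefilter model
#'
#' Each input sees a single-pole RC lowpass formed by the electrode
#' impedance R and the input capacitor C, with cutoff `1 / (2*pi*R*C)`
#' (about 3.4 kHz for 10 kOhm and 4.7 nF). `prefilter_gain` returns the
#' magnitude response of that pole.
#'
#' @param profile a [device_profile()].
#' @param freq frequency or frequencies in Hz.
#' @return cutoff frequency in Hz, or dimensionless gain.
#' @export
prefilter_cutoff <- function(profile = device_profile()) {
  R <- profile$electrode_impedance
  C <- profile$prefilter_capacitance
  if (R <= 0 || C <= 0) stop("electrode impedance and capacitance must be positive")
  1 / (2 * pi * R * C)
}

#' @rdname prefilter_cutoff
#' @export
prefilter_gain <- function(freq, profile = device_profile()) {
  1 / sqrt(1 + (freq / prefilter_cutoff(profile))^2)
}

frame_size_bytes <- function(n_channels) 3L * (as.integer(n_channels) + 1L)

#' Parse raw ADC sample frames
#'
#' The acquisition chip emits one frame per sampling period: a 24-bit
#' status word followed by one big-endian two's-complement 24-bit word per
#' channel (27 bytes for 8 channels). `parse_frames` decodes a concatenated
#' byte stream into signed integer codes; `serialize_frames` is its exact
#' inverse. Status words are retained verbatim but not interpreted.
#'
#' @param payload raw vector of concatenated frames.
#' @param n_channels channels per frame.
#' @param block a `frame_block` as returned by `parse_frames`.
#' @return `parse_frames`: a `frame_block` with `codes` (frames x channels
#'   integer matrix), `status_words`, and counts. `serialize_frames`: a raw
#'   vector byte-identical to the original payload.
#' @examples
#' pay <- as.raw(c(rep(0, 3), 0x7F, 0xFF, 0xFF, rep(0, 21)))
#' parse_frames(pay, n_channels = 8)$codes[1, 1]  # 8388607
#' @export
parse_frames <- function(payload, n_channels = 8L) {
  stopifnot(is.raw(payload))
  fb <- frame_size_bytes(n_channels)
  if (length(payload) %% fb != 0L) {
    stop("malformed frame stream: ", length(payload), " bytes is not a ",
         "multiple of the ", fb, "-byte frame; first partial frame at byte ",
         (length(payload) %/% fb) * fb)
  }
  b <- matrix(as.integer(payload), nrow = fb)
  word24 <- function(r) b[r, , drop = TRUE] * 65536L + b[r + 1L, , drop = TRUE] * 256L + b[r + 2L, , drop = TRUE]
  status <- word24(1L)
  codes <- vapply(seq_len(n_channels), function(ch) {
    w <- word24(3L * ch + 1L)
    w - ifelse(w >= 8388608L, 16777216L, 0L)  # sign-extend 24 -> 32 bit
  }, integer(ncol(b)))
  codes <- matrix(as.integer(codes), ncol = n_channels)
  structure(
    list(codes = codes, status_words = as.integer(status),
         n_frames = ncol(b), n_channels = as.integer(n_channels)),
    class = "frame_block")
}

#' @rdname parse_frames
#' @export
serialize_frames <- function(block) {
  stopifnot(inherits(block, "frame_block"))
  fb <- frame_size_bytes(block$n_channels)
  out <- matrix(0L, nrow = fb, ncol = block$n_frames)
  put24 <- function(r, w) {
    out[r, ] <<- w %/% 65536L
    out[r + 1L, ] <<- (w %/% 256L) %% 256L
    out[r + 2L, ] <<- w %% 256L
  }
  put24(1L, block$status_words)
  for (ch in seq_len(block$n_channels)) {
    w <- block$codes[, ch]
    put24(3L * ch + 1L, w + ifelse(w < 0L, 16777216L, 0L))
  }
  as.raw(out)
}

#' @export
print.frame_block <- function(x, ...) {
  cat("<frame_block> ", x$n_frames, " frames x ", x$n_channels,
      " channels\n", sep = "")
  invisible(x)
}

#' Read a raw frame dump into a recording
#'
#' Reads a binary file of concatenated ADC frames (the device's native
#' stream), converts codes to volts, and selects/labels channels.
#'
#' @param path file of concatenated frames.
#' @param profile a [device_profile()]; supplies channel count, LSB and
#'   sampling rate.
#' @param channel_map named integer vector mapping recording labels to
#'   frame channel indices.
#' @param metadata optional metadata list passed to [abr_recording()].
#' @return an [abr_recording()].
#' @export
read_frame_dump <- function(path, profile = device_profile(),
                            channel_map = c(LV = 1L, RV = 2L, LR = 3L, speaker = 4L),
                            metadata = list()) {
  payload <- readBin(path, what = "raw", n = file.size(path))
  block <- parse_frames(payload, profile$n_channels)
  volts <- codes_to_volts(block$codes, profile)
  volts <- matrix(volts, nrow = block$n_frames)
  samples <- volts[, unname(channel_map), drop = FALSE]
  colnames(samples) <- names(channel_map)
  abr_recording(samples, profile$sampling_rate, metadata = metadata)
}
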