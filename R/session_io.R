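#' Write and read recordings on disk
#'
#' The native recording format is a pair of files sharing a base path:
#' `<base>.json`, a human-readable sidecar with the format version,
#' sampling rate, channel labels, units and metadata; and `<base>.bin`,
#' the payload as little-endian 32-bit IEEE floats in volts, channel-major
#' (each channel contiguous). Time is implicit in sample indices, so long
#' recordings accumulate no timestamp drift. `read_recording(write_recording(x))`
#' reproduces samples bit-exactly (recordings are held in memory at
#' float32 precision).
#'
#' @param recording an [abr_recording()].
#' @param base_path path without extension; `.json` and `.bin` are added.
#' @return `write_recording`: `base_path`, invisibly. `read_recording`:
#'   an [abr_recording()].
#' @export
write_recording <- function(recording, base_path) {
  stopifnot(inherits(recording, "abr_recording"))
  header <- list(
    format = "abrkit-recording",
    version = 1L,
    sampling_rate = recording$sampling_rate,
    channel_labels = colnames(recording$samples),
    n_channels = ncol(recording$samples),
    n_samples = nrow(recording$samples),
    units = "volts",
    sample_format = "float32",
    byte_order = "little",
    layout = "channel-major",
    metadata = recording$metadata)
  jsonlite::write_json(header, paste0(base_path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(paste0(base_path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(recording$samples), con, size = 4L,
           endian = "little")
  invisible(base_path)
}

#' @rdname write_recording
#' @export
read_recording <- function(base_path) {
  hpath <- paste0(base_path, ".json")
  bpath <- paste0(base_path, ".bin")
  if (!file.exists(hpath)) stop("missing sidecar header: ", hpath)
  if (!file.exists(bpath)) stop("missing payload: ", bpath)
  h <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  if (!identical(h$format, "abrkit-recording")) {
    stop(hpath, " is not an abrkit recording header")
  }
  if (h$version != 1) {
    stop("unsupported recording format version ", h$version,
         " (this build reads version 1)")
  }
  if (length(h$channel_labels) != h$n_channels) {
    stop("header inconsistency in ", hpath, ": ", h$n_channels,
         " channels declared but ", length(h$channel_labels),
         " labels listed")
  }
  expected <- h$n_channels * h$n_samples * 4
  actual <- file.size(bpath)
  if (actual != expected) {
    stop("payload size mismatch in ", bpath, ": expected ", expected,
         " bytes (", h$n_samples, " x ", h$n_channels,
         " float32), found ", actual)
  }
  x <- readBin(bpath, what = "numeric", n = h$n_channels * h$n_samples,
               size = 4L, endian = "little")
  samples <- matrix(x, nrow = h$n_samples, ncol = h$n_channels)
  colnames(samples) <- h$channel_labels
  meta <- h$metadata
  if (is.null(meta)) meta <- list()
  abr_recording(samples, h$sampling_rate, metadata = as.list(meta))
}

#' Write and read a full synthetic session
#'
#' Convenience wrappers storing a [generate_session()] result as the
#' recording pair, the stimulus CSV (`<base>.stimulus.csv`) and the
#' ground-truth manifest (`<base>.manifest.json`).
#'
#' @param session an `abr_session`.
#' @param base_path path without extension.
#' @return `write_session`: `base_path` invisibly; `read_session`: a list
#'   with `recording`, `stimulus`, `manifest`.
#' @export
write_session <- function(session, base_path) {
  stopifnot(inherits(session, "abr_session"))
  write_recording(session$recording, base_path)
  write_stimulus_csv(session$stimulus, paste0(base_path, ".stimulus.csv"))
  man <- session$manifest
  man$kernel <- unclass(man$kernel)
  man$ecg <- unclass(man$ecg)
  jsonlite::write_json(man, paste0(base_path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(base_path)
}

#' @rdname write_session
#' @export
read_session <- function(base_path) {
  list(recording = read_recording(base_path),
       stimulus = read_stimulus_csv(paste0(base_path, ".stimulus.csv")),
       manifest = jsonlite::read_json(paste0(base_path, ".manifest.json"),
                                      simplifyVector = TRUE))
}

#' Session manifest
#'
#' An experiment (one anesthetic session) comprises multiple sequential
#' recordings. The manifest lists them with their speaker sides and file
#' paths. Experiments are expected to contain at least two recordings per
#' speaker side; fewer triggers a warning, not an error.
#'
#' @param subject subject id.
#' @param date experiment date string.
#' @param recordings data.frame with columns `recording`, `speaker_side`,
#'   `path` (recording base path) and `stimulus_path`.
#' @param notes free-form exclusion/quality notes.
#' @return an object of class `session_manifest`.
#' @export
session_manifest <- function(subject, date, recordings, notes = "") {
  need <- c("recording", "speaker_side", "path", "stimulus_path")
  stopifnot(is.data.frame(recordings), all(need %in% names(recordings)))
  counts <- table(recordings$speaker_side)
  if (any(counts < 2)) {
    warning("fewer than 2 recordings for speaker side(s): ",
            paste(names(counts)[counts < 2], collapse = ", "))
  }
  structure(list(subject = subject, date = date,
                 recordings = recordings, notes = notes),
            class = "session_manifest")
}

#' @rdname session_manifest
#' @param manifest a `session_manifest`.
#' @param path JSON file path.
#' @export
write_session_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname session_manifest
#' @export
read_session_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  session_manifest(m$subject, m$date, as.data.frame(m$recordings),
                   m$notes %||% "")
}
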