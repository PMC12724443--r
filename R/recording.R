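#' Multi-channel voltage recording
#'
#' Container for a raw or filtered recording: a time x channel matrix of
#' voltages plus the sampling rate and free-form metadata (subject,
#' session, recording id, speaker side, processing history).
#'
#' The standard montage is three differential electrode channels --
#' `LV` (left ear minus vertex), `RV` (right ear minus vertex),
#' `LR` (left minus right; equal to LV - RV by construction) -- plus a
#' `speaker` channel recording the voltage across the loudspeaker for
#' stimulus alignment.
#'
#' @param samples numeric matrix, time in rows, channels in columns.
#'   Column names are the channel labels.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_labels optional character vector overriding column names.
#' @param metadata named list (subject, session, recording, speaker_side, ...).
#' @return an object of class `abr_recording`.
#' @export
abr_recording <- function(samples, sampling_rate,
                          channel_labels = colnames(samples),
                          metadata = list()) {
  samples <- as.matrix(samples)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(ncol(samples)))
  }
  if (length(channel_labels) != ncol(samples)) {
    stop("channel_labels length (", length(channel_labels),
         ") does not match channel count (", ncol(samples), ")")
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  if (!(is.numeric(sampling_rate) && sampling_rate > 0)) {
    stop("sampling_rate must be a positive number")
  }
  colnames(samples) <- channel_labels
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         metadata = metadata),
    class = "abr_recording")
}

#' @export
print.abr_recording <- function(x, ...) {
  cat("<abr_recording> ", ncol(x$samples), " channel(s) [",
      paste(colnames(x$samples), collapse = ", "), "], ",
      nrow(x$samples), " samples @ ", x$sampling_rate, " Hz (",
      sprintf("%.1f", nrow(x$samples) / x$sampling_rate), " s)\n", sep = "")
  ids <- x$metadata[intersect(c("subject", "session", "recording",
                                "speaker_side"), names(x$metadata))]
  if (length(ids)) {
    cat("  ", paste(names(ids), unlist(ids), sep = "=", collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Channel accessors
#'
#' `channel()` extracts one channel as a numeric vector;
#' `electrode_channels()` lists the non-speaker channel labels.
#'
#' @param recording an [abr_recording()].
#' @param label channel label.
#' @return numeric vector / character vector.
#' @export
channel <- function(recording, label) {
  if (!label %in% colnames(recording$samples)) {
    stop("no channel '", label, "' in recording (have: ",
         paste(colnames(recording$samples), collapse = ", "), ")")
  }
  recording$samples[, label]
}

#' @rdname channel
#' @export
electrode_channels <- function(recording) {
  setdiff(colnames(recording$samples), "speaker")
}

n_samples <- function(recording) nrow(recording$samples)
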