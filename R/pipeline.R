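#' Run the full analysis pipeline
#'
#' Chains the standard stages for one or more recordings: ABR-band
#' filtering, epoching around the click onsets, 3-SD outlier-trial
#' rejection, per-level averaging, response-strength computation, and
#' per-channel threshold estimation, plus the primary-peak fit at the
#' loudest level. The pipeline is deterministic given its inputs and
#' configurations; any stage failure is re-signalled with the recording
#' id attached.
#'
#' @param sessions one of: an `abr_session` (from [generate_session()]),
#'   a list of `abr_session`-like lists with `recording` and `stimulus`
#'   elements, or a [session_manifest()] whose file paths are loaded from
#'   disk.
#' @param pipeline a [pipeline_config()].
#' @param metrics a [metric_config()].
#' @param out_dir optional directory; when given, the strength,
#'   threshold, peak and exclusion tables are written as CSV (voltages in
#'   microvolts) together with a JSON run log recording the
#'   configurations, a config hash, and the package version.
#' @return an object of class `pipeline_result`: `averaged` (list of
#'   `averaged_abr` per recording), `strengths`, `thresholds`, `peaks`,
#'   `exclusions` (data.frames), and `log`.
#' @export
run_pipeline <- function(sessions, pipeline = pipeline_config(),
                         metrics = metric_config(), out_dir = NULL) {
  if (inherits(sessions, "abr_session")) sessions <- list(sessions)
  if (inherits(sessions, "session_manifest")) {
    recs <- sessions$recordings
    sessions <- lapply(seq_len(nrow(recs)), function(i) {
      rec <- read_recording(recs$path[i])
      rec$metadata$recording <- recs$recording[i]
      rec$metadata$speaker_side <- recs$speaker_side[i]
      list(recording = rec,
           stimulus = read_stimulus_csv(recs$stimulus_path[i]))
    })
  }
  if (!length(sessions)) {
    message("empty session list: nothing to process")
    return(structure(list(averaged = list(),
                          strengths = empty_df("strength"),
                          thresholds = empty_df("threshold"),
                          peaks = empty_df("peak"),
                          exclusions = empty_df("exclusion"),
                          log = list()),
                     class = "pipeline_result"))
  }
  averaged <- list()
  strengths <- list()
  thresholds <- list()
  peaks <- list()
  exclusions <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    rec_id <- s$recording$metadata$recording %||% paste0("recording", i)
    res <- tryCatch({
      filt <- bandpass_filter(s$recording, pipeline$abr_band[1],
                              pipeline$abr_band[2], pipeline$filter_order)
      tensor <- epoch_trials(filt, s$stimulus, pipeline)
      tensor <- reject_outliers(tensor, pipeline)
      avg <- average_by_level(tensor)
      st <- strength_table(avg, metrics)
      th <- if (length(unique(st$level)) >= 2) {
        thresholds_by_channel(st, metrics)
      } else {
        empty_df("threshold")  # a threshold needs >= 2 tested levels
      }
      pk <- lapply(dimnames(avg$mean)[[3]], function(ch) {
        p <- find_primary_peak(avg, channel = ch, config = metrics)
        data.frame(channel = ch, latency_s = p$latency,
                   amplitude_v = p$amplitude, found = p$found)
      })
      list(avg = avg, st = st, th = th,
           pk = do.call(rbind, pk),
           rej = attr(tensor, "rejection"))
    }, error = function(e) {
      stop("pipeline failed for recording '", rec_id, "': ",
           conditionMessage(e), call. = FALSE)
    })
    meta <- s$recording$metadata
    tag <- function(d) {
      if (nrow(d)) {
        d$subject <- meta$subject %||% NA_character_
        d$session <- meta$session %||% NA_character_
        d$recording <- rec_id
        d$speaker_side <- meta$speaker_side %||% NA_character_
      }
      d
    }
    averaged[[rec_id]] <- res$avg
    strengths[[i]] <- tag(res$st)
    thresholds[[i]] <- tag(res$th)
    peaks[[i]] <- tag(res$pk)
    exclusions[[i]] <- tag(res$rej)
  }
  bind <- function(l) {
    l <- l[vapply(l, function(d) !is.null(d) && nrow(d) > 0, logical(1))]
    if (!length(l)) return(NULL)
    out <- do.call(rbind, l)
    rownames(out) <- NULL
    out
  }
  result <- structure(
    list(averaged = averaged,
         strengths = bind(strengths) %||% empty_df("strength"),
         thresholds = bind(thresholds) %||% empty_df("threshold"),
         peaks = bind(peaks) %||% empty_df("peak"),
         exclusions = bind(exclusions) %||% empty_df("exclusion"),
         log = list(package = "abrkit",
                    version = as.character(utils::packageVersion("abrkit")),
                    pipeline = unclass(pipeline),
                    metrics = unclass(metrics),
                    config_hash = rlang::hash(list(unclass(pipeline),
                                                   unclass(metrics))),
                    n_recordings = length(sessions))),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

empty_df <- function(kind) {
  switch(kind,
    strength = data.frame(channel = character(0), level = numeric(0),
                          strength = numeric(0), baseline = numeric(0)),
    threshold = data.frame(channel = character(0),
                           threshold_db = numeric(0),
                           censoring = character(0)),
    peak = data.frame(channel = character(0), latency_s = numeric(0),
                      amplitude_v = numeric(0), found = logical(0)),
    exclusion = data.frame(trial = integer(0), channel = character(0),
                           statistic = character(0), value = numeric(0),
                           threshold = numeric(0)))
}

#' @rdname run_pipeline
#' @param result a `pipeline_result`.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- result$strengths
  if (nrow(st)) {
    st$strength_uV <- st$strength * 1e6
    st$baseline_uV <- st$baseline * 1e6
    st$strength <- st$baseline <- NULL
  }
  utils::write.csv(st, file.path(out_dir, "strengths.csv"),
                   row.names = FALSE)
  utils::write.csv(result$thresholds, file.path(out_dir, "thresholds.csv"),
                   row.names = FALSE)
  pk <- result$peaks
  if (nrow(pk)) {
    pk$latency_ms <- pk$latency_s * 1e3
    pk$amplitude_uV <- pk$amplitude_v * 1e6
    pk$latency_s <- pk$amplitude_v <- NULL
  }
  utils::write.csv(pk, file.path(out_dir, "peaks.csv"), row.names = FALSE)
  utils::write.csv(result$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", length(x$averaged), " recording(s)\n", sep = "")
  if (nrow(x$thresholds)) {
    cat("  thresholds (dB SPL):\n")
    print(x$thresholds, row.names = FALSE)
  }
  invisible(x)
}
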