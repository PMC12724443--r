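#' Response-metric configuration
#'
#' Parameters of the peak-agnostic response quantification: the rolling-SD
#' "response strength" (1.25 ms centered window, 20 samples at 16 kHz),
#' the scalar strength read-out at t = +2.0 ms (where the rolling SD tends
#' to peak), the baseline strength read-out at t = -1.875 ms (whose window
#' spans the -2.5 to -1.25 ms baseline), the 0.3 uV threshold criterion,
#' and the search window for the early negative "primary peak".
#'
#' @param strength_window rolling window length, seconds.
#' @param scalar_time time of the scalar strength read-out, seconds.
#' @param baseline_time time of the baseline strength read-out, seconds.
#' @param threshold_criterion strength criterion defining threshold, volts.
#' @param peak_search_window length-2 seconds, primary-peak search range.
#' @param min_peak_correlation cross-correlation floor below which a level
#'   is excluded from the latency fit.
#' @param max_lag largest cross-correlation lag considered, seconds. The
#'   default is half the ~1 ms oscillation period of the response: wider
#'   windows invite cycle skipping, because the cross-correlation of a
#'   quasi-periodic wavelet has secondary peaks one carrier period away.
#' @return an object of class `metric_config`.
#' @export
metric_config <- function(strength_window = 0.00125,
                          scalar_time = 0.0020,
                          baseline_time = -0.001875,
                          threshold_criterion = 3e-7,
                          peak_search_window = c(5e-4, 2.5e-3),
                          min_peak_correlation = 0.3,
                          max_lag = 5e-4) {
  stopifnot(strength_window > 0, threshold_criterion > 0,
            length(peak_search_window) == 2,
            peak_search_window[1] < peak_search_window[2],
            max_lag > 0)
  structure(as.list(environment()), class = "metric_config")
}

#' Rolling-SD response strength of a waveform
#'
#' The response strength at a timepoint is the sample standard deviation
#' (denominator n - 1) of the waveform over a `window`-second window
#' centered on it. Edges where the full window does not fit are NA.
#' Strength is invariant to constant offsets and scales with the
#' waveform's amplitude.
#'
#' @param waveform numeric vector, volts.
#' @param sampling_rate Hz.
#' @param window window length in seconds.
#' @return numeric vector of strengths, same length as `waveform`.
#' @export
rolling_strength <- function(waveform, sampling_rate, window = 0.00125) {
  rolling_sd(waveform, round(window * sampling_rate))
}

#' Strength table of an averaged ABR
#'
#' Computes, for every (channel, level) cell of an [average_by_level()]
#' result, the scalar response strength at `scalar_time` and the baseline
#' strength at `baseline_time` (nearest sample with a defined rolling
#' window).
#'
#' @param avg an `averaged_abr`.
#' @param config a [metric_config()].
#' @return data.frame with columns `channel`, `level`, `strength`
#'   (volts), `baseline` (volts).
#' @export
strength_table <- function(avg, config = metric_config()) {
  stopifnot(inherits(avg, "averaged_abr"))
  chans <- dimnames(avg$mean)[[3]]
  at_time <- function(s, t0) {
    ok <- which(!is.na(s))
    ok[which.min(abs(avg$time[ok] - t0))]
  }
  out <- expand.grid(channel = chans, level = avg$levels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$strength <- NA_real_
  out$baseline <- NA_real_
  for (i in seq_len(nrow(out))) {
    li <- as.character(out$level[i])
    s <- rolling_strength(avg$mean[li, , out$channel[i]],
                          avg$sampling_rate, config$strength_window)
    out$strength[i] <- s[at_time(s, config$scalar_time)]
    out$baseline[i] <- s[at_time(s, config$baseline_time)]
  }
  out
}

#' Interpolated hearing threshold from strengths per level
#'
#' The threshold is the sound level at which the response strength
#' crosses `threshold_criterion`, obtained by linear interpolation
#' between tested levels. Levels are scanned for the highest level whose
#' strength is below the criterion while the next tested level is at or
#' above it (robust to spurious low-level bumps). If the strength is at
#' or above the criterion at every level the estimate is censored
#' `below_grid` (threshold reported at the grid minimum); if it never
#' reaches the criterion it is censored `above_grid` (reported at the
#' grid maximum).
#'
#' @param levels tested levels, dB SPL.
#' @param strengths scalar strengths at those levels, volts.
#' @param config a [metric_config()] (or a numeric criterion in volts).
#' @return an object of class `threshold_estimate`: `threshold` (dB SPL),
#'   `censoring` ("none", "below_grid", "above_grid"), `crossing_levels`.
#' @examples
#' estimate_threshold(c(33, 37), c(0.25e-6, 0.35e-6))  # 35 dB SPL
#' @export
estimate_threshold <- function(levels, strengths, config = metric_config()) {
  crit <- if (is.numeric(config)) config else config$threshold_criterion
  ok <- !is.na(strengths)
  levels <- levels[ok]
  strengths <- strengths[ok]
  if (length(levels) < 2) {
    stop("threshold estimation needs at least 2 levels with defined strength")
  }
  o <- order(levels)
  levels <- levels[o]
  strengths <- strengths[o]
  below <- strengths < crit
  res <- function(th, cens, cross = numeric(0)) {
    structure(list(threshold = th, censoring = cens,
                   crossing_levels = cross, criterion = crit),
              class = "threshold_estimate")
  }
  if (!any(below)) return(res(min(levels), "below_grid"))
  if (all(below)) return(res(max(levels), "above_grid"))
  i <- max(which(below[-length(below)] & !below[-1]))
  th <- levels[i] + (crit - strengths[i]) *
    (levels[i + 1] - levels[i]) / (strengths[i + 1] - strengths[i])
  res(th, "none", levels[c(i, i + 1)])
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<threshold_estimate> %.1f dB SPL (%s)\n", x$threshold,
              if (x$censoring == "none") "uncensored" else
                paste("censored", x$censoring)))
  invisible(x)
}

#' Thresholds for every channel of an averaged ABR
#'
#' @param avg an `averaged_abr` (or a [strength_table()] data.frame).
#' @param config a [metric_config()].
#' @return data.frame with columns `channel`, `threshold_db`, `censoring`.
#' @export
thresholds_by_channel <- function(avg, config = metric_config()) {
  st <- if (is.data.frame(avg)) avg else strength_table(avg, config)
  out <- lapply(split(st, st$channel), function(d) {
    est <- estimate_threshold(d$level, d$strength, config)
    data.frame(channel = d$channel[1], threshold_db = est$threshold,
               censoring = est$censoring)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Locate the primary peak
#'
#' The primary peak is the large early negative deflection (~1.4 ms) of
#' the response at the loudest level. The most negative sample within
#' `peak_search_window` is refined by parabolic interpolation over three
#' samples. A waveform with no interior negative minimum in the window
#' (e.g. monotone or sign-flipped) returns `found = FALSE`.
#'
#' @param x an `averaged_abr` (uses the loudest level) or a numeric
#'   waveform.
#' @param ... passed to methods.
#' @return list with `latency` (s), `amplitude` (V, negative), `found`.
#' @export
find_primary_peak <- function(x, ...) UseMethod("find_primary_peak")

#' @rdname find_primary_peak
#' @param time time axis in seconds (for the default method).
#' @param config a [metric_config()].
#' @export
find_primary_peak.default <- function(x, time, config = metric_config(), ...) {
  win <- which(time >= config$peak_search_window[1] &
               time <= config$peak_search_window[2])
  if (length(win) < 3) stop("peak search window contains fewer than 3 samples")
  i <- win[which.min(x[win])]
  interior <- i > win[1] && i < win[length(win)]
  if (x[i] >= 0 || !interior ||
      !(x[i] <= x[i - 1] && x[i] <= x[i + 1])) {
    return(list(latency = NA_real_, amplitude = NA_real_, found = FALSE))
  }
  v <- parabolic_vertex(x[i - 1], x[i], x[i + 1])
  dt <- time[2] - time[1]
  list(latency = time[i] + v$offset * dt, amplitude = v$value, found = TRUE)
}

#' @rdname find_primary_peak
#' @param channel channel label.
#' @export
find_primary_peak.averaged_abr <- function(x, channel = "LV",
                                           config = metric_config(), ...) {
  li <- as.character(max(x$levels))
  find_primary_peak(x$mean[li, , channel], x$time, config)
}

# Normalized cross-correlation of y against ref over integer lags
# -max_lag..max_lag (samples); positive lag means y is delayed.
xcorr_lags <- function(ref, y, max_lag) {
  n <- length(ref)
  lags <- -max_lag:max_lag
  r <- vapply(lags, function(tau) {
    if (tau >= 0) {
      a <- ref[1:(n - tau)]
      b <- y[(1 + tau):n]
    } else {
      a <- ref[(1 - tau):n]
      b <- y[1:(n + tau)]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  list(lags = lags, r = r)
}

#' Latency shift across sound levels
#'
#' Lower sound levels evoke a delayed response. For each level the lag of
#' its averaged waveform relative to the loudest level is estimated as
#' the peak of the normalized cross-correlation, refined to sub-sample
#' precision by parabolic interpolation (the 62.5 us sampling period is
#' far coarser than the ~7 us/dB effect). A least-squares line of lag
#' versus dB below the loudest level gives the latency slope. Levels
#' whose correlation peak is below `min_peak_correlation` (no detectable
#' response) or at the lag-window edge are excluded with a warning.
#'
#' @param avg an `averaged_abr` with >= 3 levels.
#' @param channel channel label.
#' @param config a [metric_config()].
#' @return an object of class `latency_fit`: `table` (level, lag_s,
#'   peak_r, used), `slope_s_per_db`, `intercept_s`, `channel`.
#' @export
latency_shift <- function(avg, channel = "LV", config = metric_config()) {
  stopifnot(inherits(avg, "averaged_abr"))
  if (length(avg$levels) < 3) stop("latency fit needs at least 3 levels")
  fs <- avg$sampling_rate
  top <- max(avg$levels)
  ref <- avg$mean[as.character(top), , channel]
  ml <- round(config$max_lag * fs)
  tab <- data.frame(level = avg$levels, lag_s = NA_real_,
                    peak_r = NA_real_, used = FALSE)
  for (li in seq_along(avg$levels)) {
    y <- avg$mean[as.character(avg$levels[li]), , channel]
    xc <- xcorr_lags(ref, y, ml)
    k <- which.max(xc$r)
    tab$peak_r[li] <- xc$r[k]
    if (is.na(xc$r[k]) || xc$r[k] < config$min_peak_correlation) next
    if (k == 1 || k == length(xc$r)) {
      warning("correlation peak at lag-window edge for level ",
              avg$levels[li], " dB; level excluded")
      next
    }
    v <- parabolic_vertex(xc$r[k - 1], xc$r[k], xc$r[k + 1])
    tab$lag_s[li] <- (xc$lags[k] + v$offset) / fs
    tab$used[li] <- TRUE
  }
  used <- tab[tab$used, ]
  if (nrow(used) < 3) {
    stop("fewer than 3 levels with a detectable response; cannot fit ",
         "a latency slope")
  }
  fit <- stats::lm(lag_s ~ I(top - level), data = used)
  structure(
    list(table = tab,
         slope_s_per_db = unname(stats::coef(fit)[2]),
         intercept_s = unname(stats::coef(fit)[1]),
         channel = channel),
    class = "latency_fit")
}

#' @export
print.latency_fit <- function(x, ...) {
  cat(sprintf("<latency_fit> %s: %.2f us/dB over %d level(s)\n",
              x$channel, x$slope_s_per_db * 1e6, sum(x$table$used)))
  invisible(x)
}

#' Session-to-session waveform correlations
#'
#' Pearson correlation between the loudest-level averaged waveforms of
#' two session lists (e.g. day 1 and day 2 of the same cohort). Entries
#' whose subjects match are "within-subject"; the rest are
#' "across-subject".
#'
#' @param day1,day2 lists of `averaged_abr` objects on a common time grid.
#' @param subjects1,subjects2 subject ids (default: recording metadata).
#' @param channel channel label.
#' @return an object of class `waveform_correlation`: the r `matrix`
#'   (day1 rows x day2 columns) and `within` / `across` summaries
#'   (mean, sd, n).
#' @export
waveform_correlation <- function(day1, day2 = day1,
                                 subjects1 = vapply(day1, function(a)
                                   a$metadata$subject %||% NA_character_,
                                   character(1)),
                                 subjects2 = vapply(day2, function(a)
                                   a$metadata$subject %||% NA_character_,
                                   character(1)),
                                 channel = "LV") {
  flat <- function(a) a$mean[as.character(max(a$levels)), , channel]
  w1 <- lapply(day1, flat)
  w2 <- lapply(day2, flat)
  m <- matrix(NA_real_, length(w1), length(w2),
              dimnames = list(subjects1, subjects2))
  for (i in seq_along(w1)) {
    for (j in seq_along(w2)) {
      if (stats::sd(w1[[i]]) == 0 || stats::sd(w2[[j]]) == 0) {
        warning("zero-variance waveform; correlation undefined for pair (",
                i, ", ", j, ")")
        next
      }
      m[i, j] <- stats::cor(w1[[i]], w2[[j]])
    }
  }
  same <- outer(subjects1, subjects2, `==`)
  summ <- function(v) c(mean = mean(v, na.rm = TRUE),
                        sd = stats::sd(v, na.rm = TRUE),
                        n = sum(!is.na(v)))
  structure(list(matrix = m,
                 within = summ(m[same]),
                 across = summ(m[!same])),
            class = "waveform_correlation")
}

#' @export
print.waveform_correlation <- function(x, ...) {
  cat(sprintf("<waveform_correlation> within r = %.3f +/- %.3f (n=%d), ",
              x$within["mean"], x$within["sd"], x$within["n"]))
  cat(sprintf("across r = %.3f +/- %.3f (n=%d)\n",
              x$across["mean"], x$across["sd"], x$across["n"]))
  invisible(x)
}

#' Pre/post hearing threshold shift
#'
#' Per-subject threshold shift between two condition tables (for example
#' before and after a hearing-loss intervention): thresholds are averaged
#' within subject for each condition, shifts are `post - pre`, and the
#' summary is their mean and SD across subjects. Estimates censored
#' `above_grid` in the post condition make the reported shift a lower
#' bound, which is flagged.
#'
#' @param pre,post data.frames with columns `subject`, `threshold_db`,
#'   and optionally `censoring`. Subject sets must match.
#' @return an object of class `threshold_shift`: `per_subject`
#'   (data.frame), `mean_shift_db`, `sd_shift_db`, `lower_bound`.
#' @export
threshold_shift <- function(pre, post) {
  need <- c("subject", "threshold_db")
  stopifnot(all(need %in% names(pre)), all(need %in% names(post)))
  if (!setequal(unique(pre$subject), unique(post$subject))) {
    stop("pre and post subject sets differ: {",
         paste(setdiff(unique(pre$subject), unique(post$subject)),
               collapse = ","), "} vs {",
         paste(setdiff(unique(post$subject), unique(pre$subject)),
               collapse = ","), "}")
  }
  agg <- function(d) {
    out <- stats::aggregate(threshold_db ~ subject, data = d, FUN = mean)
    cens <- if ("censoring" %in% names(d)) {
      stats::aggregate(censoring ~ subject, data = d,
                       FUN = function(x) any(x == "above_grid"))
    } else data.frame(subject = out$subject, censoring = FALSE)
    merge(out, cens, by = "subject")
  }
  a <- agg(pre)
  b <- agg(post)
  d <- merge(a, b, by = "subject", suffixes = c("_pre", "_post"))
  d$shift_db <- d$threshold_db_post - d$threshold_db_pre
  d$lower_bound <- d$censoring_post
  structure(
    list(per_subject = d[, c("subject", "threshold_db_pre",
                             "threshold_db_post", "shift_db",
                             "lower_bound")],
         mean_shift_db = mean(d$shift_db),
         sd_shift_db = stats::sd(d$shift_db),
         lower_bound = any(d$lower_bound)),
    class = "threshold_shift")
}

#' @export
print.threshold_shift <- function(x, ...) {
  cat(sprintf("<threshold_shift> %s%.1f +/- %.1f dB over %d subject(s)\n",
              if (x$lower_bound) ">= " else "",
              x$mean_shift_db, x$sd_shift_db, nrow(x$per_subject)))
  invisible(x)
}

#' Baseline noise versus trial count
#'
#' Empirical check of the averaging noise law: for a doubling grid of
#' trial counts n, average n randomly subsampled included trials and
#' compute the baseline rms of the mean (averaged over `n_resample`
#' subsamples); then fit the log-log slope of rms versus n. Independent
#' trials give a slope of -1/2.
#'
#' @param tensor a [trial_tensor] with >= 16 included trials.
#' @param channel channel label.
#' @param n_grid trial counts (default 4, 8, ... up to the trial count;
#'   values beyond it are dropped with a warning).
#' @param n_resample subsamples averaged per grid point.
#' @param seed RNG seed for the subsampling.
#' @param baseline_window length-2 seconds (half-open).
#' @return an object of class `noise_floor_curve`: `table` (n, rms) and
#'   `slope` from the log-log fit.
#' @export
noise_floor_curve <- function(tensor, channel = "LV",
                              n_grid = NULL, n_resample = 32, seed = 1,
                              baseline_window = c(-0.0025, -0.00125)) {
  stopifnot(inherits(tensor, "trial_tensor"))
  inc <- which(tensor$include)
  if (length(inc) < 16) stop("noise floor curve needs >= 16 included trials")
  if (is.null(n_grid)) {
    n_grid <- 2^(2:floor(log2(length(inc))))
  } else if (any(n_grid > length(inc))) {
    warning("n grid truncated to the ", length(inc), " included trials")
    n_grid <- n_grid[n_grid <= length(inc)]
  }
  bidx <- tensor$time >= baseline_window[1] & tensor$time < baseline_window[2]
  e <- tensor$epochs[, bidx, channel]
  set.seed(seed)
  rms_n <- vapply(n_grid, function(nn) {
    mean(vapply(seq_len(n_resample), function(k) {
      rows <- sample(inc, nn)
      rms(colMeans(e[rows, , drop = FALSE]))
    }, numeric(1)))
  }, numeric(1))
  fit <- stats::lm(log(rms_n) ~ log(n_grid))
  structure(list(table = data.frame(n = n_grid, rms = rms_n),
                 slope = unname(stats::coef(fit)[2])),
            class = "noise_floor_curve")
}

#' @export
print.noise_floor_curve <- function(x, ...) {
  cat(sprintf("<noise_floor_curve> slope %.3f over n = %d..%d\n",
              x$slope, min(x$table$n), max(x$table$n)))
  invisible(x)
}
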