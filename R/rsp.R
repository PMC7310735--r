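#' Construct a breath series
#'
#' Chest-rise peak instants and the intervals between them.
#'
#' @param breath_peak_times Peak instants, seconds, increasing.
#' @return Object of class `breath_series` with fields `breath_peak_times`
#'   (s), `breath_intervals` (ms) and `interval_end_times` (s).
#' @export
breath_series <- function(breath_peak_times) {
  breath_peak_times <- as.numeric(breath_peak_times)
  if (is.unsorted(breath_peak_times, strictly = TRUE)) {
    stop("breath peak times must be strictly increasing")
  }
  iv <- if (length(breath_peak_times) >= 2L) {
    diff(breath_peak_times) * 1000
  } else numeric(0)
  structure(list(breath_peak_times = breath_peak_times,
                 breath_intervals = iv,
                 interval_end_times = breath_peak_times[-1L]),
            class = "breath_series")
}

#' @export
print.breath_series <- function(x, ...) {
  cat(sprintf("<breath_series> %d peaks (mean interval %.0f ms)\n",
              length(x$breath_peak_times),
              if (length(x$breath_intervals)) mean(x$breath_intervals)
              else NA_real_))
  invisible(x)
}

#' Detect breaths from a chest-displacement record
#'
#' Band-pass filters the signal to the breathing band and counts chest rises
#' as local maxima at least 2.5 s apart. The upper cutoff defaults to 0.4 Hz
#' (24 breaths per minute); the lower to 0.1 Hz (6/min). A literal 24 Hz
#' upper cutoff is available for audit via `literal_cutoff` (it only removes
#' high-frequency noise and keeps the offset removal of the 0.1 Hz edge).
#'
#' @param record A `biosignal_record` with channel `"rsp"`.
#' @param literal_cutoff Use 24 Hz as the upper band edge instead of 0.4 Hz.
#' @param min_peak_dist_s Minimum spacing between breath peaks, seconds. Must
#'   stay below the period of the upper band edge (2.5 s at 0.4 Hz) or
#'   breaths at the edge rate are suppressed.
#' @return A `breath_series`; empty for a flat signal.
#' @export
detect_breaths <- function(record, literal_cutoff = FALSE,
                           min_peak_dist_s = 2) {
  stopifnot(inherits(record, "biosignal_record"))
  if (record$channel != "rsp") stop("detect_breaths needs an rsp record")
  fs <- record$sampling_rate
  x <- record$samples
  if (length(x) < 3L || stats::sd(x) < 1e-12) return(breath_series(numeric(0)))
  hi <- if (literal_cutoff) min(24, 0.99 * fs / 2) else 0.4
  y <- butter_filtfilt(x, fs, c(0.1, hi), "pass", order = 2L)
  if (stats::sd(y) < 1e-12) return(breath_series(numeric(0)))
  pks <- local_maxima(y, min_dist = max(1L, round(min_peak_dist_s * fs)))
  # keep rises: peaks above zero with some amplitude relative to the band
  pks <- pks[y[pks] > 0.1 * stats::sd(y)]
  breath_series(record$t0 + (pks - 1L) / fs)
}

#' Canonical RSP feature names
#' @return Character vector of the 7 RSP feature names in canonical order.
#' @export
rsp_feature_names <- function() {
  c("BRNmean", "BRstd", "BRNFD", "BRNSD", "BRV", "BRavNN", "BRsdNN")
}

#' RSP features for one window
#'
#' The 7 respiration features with the same conventions as the ECG features,
#' applied to the breath-interval sequence and the breath-wise breathing-rate
#' series: normalized mean BR (window mean minus the resting mean), standard
#' deviation and normalized first/second differences of the BR series, the
#' signed-difference variability statistic, and mean/standard deviation of
#' the breath intervals. Windows with fewer than 3 breaths (the normal case
#' for 10-s windows) yield missing flags.
#'
#' @param breaths A `breath_series`.
#' @param window Length-2 numeric `(start, end)`, seconds, half-open.
#' @param baseline An `anx_baseline` providing `br_rest_mean`.
#' @return List with `values` (named numeric) and `missing` (named logical).
#' @export
rsp_features <- function(breaths, window, baseline) {
  stopifnot(inherits(breaths, "breath_series"),
            inherits(baseline, "anx_baseline"))
  vals <- stats::setNames(rep(NA_real_, 7L), rsp_feature_names())
  in_w <- breaths$interval_end_times >= window[1L] &
    breaths$interval_end_times < window[2L]
  iv <- breaths$breath_intervals[in_w]
  n_pk <- sum(breaths$breath_peak_times >= window[1L] &
                breaths$breath_peak_times < window[2L])
  if (n_pk >= 3L && length(iv) >= 2L && !is.na(baseline$br_rest_mean)) {
    br <- 60000 / iv
    vals["BRNmean"] <- mean(br - baseline$br_rest_mean)
    sdf <- stat_diff_features(br)
    vals["BRstd"] <- sdf[["std"]]
    vals["BRNFD"] <- sdf[["NFD"]]
    vals["BRNSD"] <- sdf[["NSD"]]
    ivf <- interval_features(iv)
    vals["BRV"] <- ivf[["HRV"]]
    vals["BRavNN"] <- ivf[["avNN"]]
    vals["BRsdNN"] <- ivf[["sdNN"]]
  }
  list(values = vals, missing = is.na(vals))
}
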