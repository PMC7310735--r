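#' Tonic EDA filter
#'
#' Zero-phase second-order Butterworth low-pass at 1.5 Hz. The filtered
#' series is the basis for the statistical EDA features and for the rest-span
#' extrema of the range correction.
#'
#' @param record A `biosignal_record` with channel `"eda"`.
#' @param cutoff_hz Low-pass cutoff, Hz.
#' @return A `biosignal_record` with the filtered samples.
#' @export
tonic_filter <- function(record, cutoff_hz = 1.5) {
  stopifnot(inherits(record, "biosignal_record"))
  if (record$channel != "eda") stop("tonic_filter needs an eda record")
  y <- butter_filtfilt(record$samples, record$sampling_rate, cutoff_hz,
                       "low", order = 2L)
  biosignal_record("eda", y, record$sampling_rate, record$t0)
}

#' Phasic EDA filter
#'
#' Produces the phasic skin-conductance signal: the 1.5 Hz low-passed series
#' is high-passed at 0.05 Hz, removing the tonic level and slow drift while
#' preserving skin conductance responses. The high-pass is a zero-phase
#' first-order Butterworth pass (an effective second-order magnitude
#' response), which keeps post-response undershoot small relative to the
#' 0.03 uS detection threshold.
#'
#' @param record A `biosignal_record` with channel `"eda"`.
#' @param highpass_hz High-pass cutoff, Hz.
#' @param lowpass_hz Smoothing low-pass applied first, Hz.
#' @return A `biosignal_record` with the phasic samples.
#' @export
phasic_filter <- function(record, highpass_hz = 0.05, lowpass_hz = 1.5) {
  stopifnot(inherits(record, "biosignal_record"))
  if (record$channel != "eda") stop("phasic_filter needs an eda record")
  y <- butter_filtfilt(record$samples, record$sampling_rate, lowpass_hz,
                       "low", order = 2L)
  y <- butter_filtfilt(y, record$sampling_rate, highpass_hz,
                       "high", order = 1L)
  biosignal_record("eda", y, record$sampling_rate, record$t0)
}

#' Detect orienting responses in a phasic EDA series
#'
#' Scores skin conductance responses: local maxima of the phasic signal whose
#' rise from the preceding trough (the onset) reaches the detection threshold
#' of 0.03 uS. The offset is the half-recovery point -- the first sample
#' after the peak where the signal falls below onset amplitude plus half the
#' response magnitude -- capped at 10 s after the peak. Overlapping responses
#' are split at the intervening local minimum because each onset is the
#' preceding trough.
#'
#' @param phasic A `biosignal_record` holding the phasic series (see
#'   [phasic_filter()]).
#' @param window Length-2 numeric `(start, end)`, seconds; responses whose
#'   peak lies in the half-open window are returned. Defaults to the full
#'   series.
#' @param threshold Minimum response magnitude, uS.
#' @param max_recovery_s Cap on the offset search after the peak, seconds.
#' @return `data.frame` with columns `onset_t`, `peak_t`, `offset_t`
#'   (seconds), `magnitude` (uS) and `duration` (s); zero rows if none.
#' @export
detect_orienting_responses <- function(phasic, window = NULL,
                                       threshold = 0.03,
                                       max_recovery_s = 10) {
  stopifnot(inherits(phasic, "biosignal_record"))
  x <- phasic$samples
  fs <- phasic$sampling_rate
  tt <- record_times(phasic)
  empty <- data.frame(onset_t = numeric(0), peak_t = numeric(0),
                      offset_t = numeric(0), magnitude = numeric(0),
                      duration = numeric(0))
  n <- length(x)
  if (n < 3L || stats::sd(x) < 1e-15) return(empty)
  pks <- local_maxima(x, min_dist = max(1L, round(0.25 * fs)))
  if (!length(pks)) return(empty)
  # troughs: weak local minima plus the series start; using the last trough
  # before a peak puts the onset at the end of any flat stretch, i.e. where
  # the rise actually starts
  weak_min <- which(x[2:(n - 1L)] <= x[1:(n - 2L)] &
                      x[2:(n - 1L)] <= x[3:n]) + 1L
  trs <- sort(unique(c(1L, weak_min)))
  out <- vector("list", length(pks))
  k <- 0L
  for (p in pks) {
    prior <- trs[trs < p]
    if (!length(prior)) next
    on <- prior[length(prior)]
    mag <- x[p] - x[on]
    if (mag < threshold) next
    half_level <- x[on] + 0.5 * mag
    cap <- min(n, p + round(max_recovery_s * fs))
    seg <- x[p:cap]
    below <- which(seg < half_level)
    off <- if (length(below)) p + below[1L] - 1L else cap
    k <- k + 1L
    out[[k]] <- data.frame(onset_t = tt[on], peak_t = tt[p],
                           offset_t = tt[off], magnitude = mag,
                           duration = tt[off] - tt[on])
  }
  if (!k) return(empty)
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[order(res$peak_t), , drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(window)) {
    res <- res[res$peak_t >= window[1L] & res$peak_t < window[2L], ,
               drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

#' Canonical EDA feature names
#' @return Character vector of the 7 EDA feature names in canonical order.
#' @export
eda_feature_names <- function() {
  c("EDANmean", "EDAstd", "EDANFD", "EDANSD", "EDAnOR", "EDAmmOR", "EDAmdOR")
}

#' EDA features for one window
#'
#' The 7 EDA features: the range-corrected normalized mean (each tonic sample
#' referenced to the resting-phase minimum and scaled by the resting range,
#' after Lykken), standard deviation and normalized first/second differences
#' of the tonic window, and the orienting-response summary (count, mean
#' magnitude, mean duration) from the phasic window. With zero responses the
#' magnitude/duration means are `NA` with missing flags, never silently zero.
#'
#' @param tonic,phasic `biosignal_record`s from [tonic_filter()] and
#'   [phasic_filter()] covering the window.
#' @param window Length-2 numeric `(start, end)`, seconds, half-open.
#' @param baseline An `anx_baseline`; its `eda_rest_min`/`eda_rest_max` must
#'   differ (a zero resting range leaves the normalization undefined).
#' @param threshold Orienting-response detection threshold, uS.
#' @return List with `values` (named numeric) and `missing` (named logical).
#' @export
eda_features <- function(tonic, phasic, window, baseline, threshold = 0.03) {
  stopifnot(inherits(baseline, "anx_baseline"))
  rng <- baseline$eda_rest_max - baseline$eda_rest_min
  if (!is.finite(rng) || rng <= 0) {
    stop("degenerate baseline: resting EDA range is zero")
  }
  tw <- slice_record(tonic, window[1L], window[2L])
  vals <- stats::setNames(rep(NA_real_, 7L), eda_feature_names())
  if (length(tw$samples)) {
    vals["EDANmean"] <- mean((tw$samples - baseline$eda_rest_min) / rng)
    sdf <- stat_diff_features(tw$samples)
    vals["EDAstd"] <- sdf[["std"]]
    vals["EDANFD"] <- sdf[["NFD"]]
    vals["EDANSD"] <- sdf[["NSD"]]
  }
  ors <- detect_orienting_responses(phasic, window, threshold = threshold)
  vals["EDAnOR"] <- nrow(ors)
  if (nrow(ors)) {
    vals["EDAmmOR"] <- mean(ors$magnitude)
    vals["EDAmdOR"] <- mean(ors$duration)
  }
  list(values = vals, missing = is.na(vals))
}

#' Export orienting responses as CSV
#' @param responses Output of [detect_orienting_responses()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_or_csv <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}
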