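#' Construct an NNI series
#'
#' R-peak instants plus the normal-to-normal intervals derived from them.
#' Intervals outside the physiological plausibility band `[300, 2000]` ms are
#' excluded; the retained intervals keep the time of their ending peak so
#' window membership can be decided.
#'
#' @param peak_times R-peak instants, seconds (session clock), increasing.
#' @param plausible_ms Length-2 plausibility band for intervals, ms.
#' @return Object of class `nni_series` with fields `peak_times`, `nni` (ms)
#'   and `nni_end_times` (s).
#' @export
nni_series <- function(peak_times, plausible_ms = c(300, 2000)) {
  peak_times <- as.numeric(peak_times)
  if (is.unsorted(peak_times, strictly = TRUE)) {
    stop("peak_times must be strictly increasing")
  }
  if (length(peak_times) >= 2L) {
    nni <- diff(peak_times) * 1000
    keep <- nni >= plausible_ms[1L] & nni <= plausible_ms[2L]
    nni <- nni[keep]
    end_t <- peak_times[-1L][keep]
  } else {
    nni <- numeric(0)
    end_t <- numeric(0)
  }
  structure(list(peak_times = peak_times, nni = nni, nni_end_times = end_t),
            class = "nni_series")
}

#' @export
print.nni_series <- function(x, ...) {
  cat(sprintf("<nni_series> %d peaks, %d plausible NNIs (mean %.0f ms)\n",
              length(x$peak_times), length(x$nni),
              if (length(x$nni)) mean(x$nni) else NA_real_))
  invisible(x)
}

# Zero-phase Butterworth helper. signal::filtfilt squares the magnitude
# response; order here is the order of the underlying butter design. The
# input is extended by odd reflection at both ends so startup transients do
# not leak into the series (important for the slow EDA filters, whose settle
# time is long relative to a window).
butter_filtfilt <- function(x, fs, cutoff, type, order = 2L) {
  w <- cutoff / (fs / 2)
  if (any(w <= 0) || any(w >= 1)) stop("cutoff outside (0, Nyquist)")
  bf <- signal::butter(order, w, type = type)
  n <- length(x)
  p <- min(n - 1L, as.integer(ceiling(3 * fs / min(cutoff))))
  if (p < 1L) return(as.numeric(signal::filtfilt(bf, x)))
  head_pad <- 2 * x[1L] - x[(p + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - p)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  as.numeric(y[(p + 1L):(p + n)])
}

#' Detect R-peaks with the Pan-Tompkins algorithm
#'
#' The six classical stages: band-pass 5--12 Hz, differentiation, squaring,
#' 150-ms moving-window integration, adaptive dual-level thresholding with a
#' 200-ms refractory period, and decision rules including a search-back at
#' 1.66x the running RR mean. Peak positions are refined to the maximum of
#' the band-passed signal near each accepted integrator peak.
#'
#' @param record A `biosignal_record` with channel `"ecg"`, at least 5 s long.
#' @return An `nni_series`. A flat or empty-energy signal yields zero peaks.
#' @export
detect_r_peaks <- function(record) {
  stopifnot(inherits(record, "biosignal_record"))
  if (record$channel != "ecg") stop("detect_r_peaks needs an ecg record")
  fs <- record$sampling_rate
  x <- record$samples
  if (length(x) / fs < 5) stop("ECG record shorter than 5 s")
  if (stats::sd(x) < 1e-12) return(nni_series(numeric(0)))

  # stage 1: band-pass 5-12 Hz (zero phase, so no group-delay bookkeeping)
  xf <- butter_filtfilt(x, fs, c(5, 12), "pass", order = 2L)
  # stage 2: five-point derivative
  h <- c(1, 2, 0, -2, -1) * (fs / 8)
  xd <- as.numeric(stats::filter(xf, h, sides = 2))
  xd[is.na(xd)] <- 0
  # stage 3: squaring
  xs <- xd^2
  # stage 4: moving-window integration, 150 ms
  w <- max(1L, round(0.150 * fs))
  xi <- as.numeric(stats::filter(xs, rep(1 / w, w), sides = 2))
  xi[is.na(xi)] <- 0

  # candidate peaks of the integrated signal, >= 200 ms apart
  refr <- round(0.200 * fs)
  cand <- local_maxima(xi, min_dist = refr)
  if (!length(cand)) return(nni_series(numeric(0)))

  # stages 5-6: adaptive thresholds + search-back
  init_n <- min(length(xi), round(2 * fs))
  spki <- max(xi[seq_len(init_n)]) * 0.5
  npki <- mean(xi[seq_len(init_n)]) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)
  qrs_idx <- integer(0)
  noise_idx <- integer(0)
  rr_hist <- numeric(0)
  for (i in seq_along(cand)) {
    p <- cand[i]
    v <- xi[p]
    accepted <- FALSE
    if (v > thr1) {
      if (!length(qrs_idx) || (p - qrs_idx[length(qrs_idx)]) > refr) {
        qrs_idx <- c(qrs_idx, p)
        spki <- 0.125 * v + 0.875 * spki
        accepted <- TRUE
      }
    }
    if (!accepted) {
      noise_idx <- c(noise_idx, p)
      npki <- 0.125 * v + 0.875 * npki
      # search-back: missed beat if gap exceeds 1.66x running RR mean
      nq <- length(qrs_idx)
      if (nq >= 2L) {
        rr_mean <- mean(utils::tail(diff(qrs_idx), 8L))
        if ((p - qrs_idx[nq]) > 1.66 * rr_mean) {
          back <- noise_idx[noise_idx > qrs_idx[nq] & noise_idx <= p]
          if (length(back)) {
            bb <- back[which.max(xi[back])]
            if (xi[bb] > 0.5 * thr1 && (bb - qrs_idx[nq]) > refr) {
              qrs_idx <- sort(c(qrs_idx, bb))
              spki <- 0.25 * xi[bb] + 0.75 * spki
            }
          }
        }
      }
    }
    thr1 <- npki + 0.25 * (spki - npki)
  }
  if (!length(qrs_idx)) return(nni_series(numeric(0)))

  # refine to the band-passed maximum within +/-75 ms of each accepted peak
  half <- round(0.075 * fs)
  ref <- vapply(qrs_idx, function(p) {
    lo <- max(1L, p - half); hi <- min(length(xf), p + half)
    as.integer(lo + which.max(xf[lo:hi]) - 1L)
  }, integer(1))
  ref <- sort(unique(ref))
  # enforce refractory after refinement
  if (length(ref) > 1L) {
    keep <- c(TRUE, diff(ref) > refr)
    while (!all(keep)) {
      ref <- ref[keep]
      keep <- c(TRUE, diff(ref) > refr)
    }
  }
  nni_series(record$t0 + (ref - 1L) / fs)
}

# indices of local maxima at least min_dist samples apart (greedy by height)
local_maxima <- function(x, min_dist) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  is_max <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                    x[2:(n - 1L)] >= x[3:n]) + 1L
  if (!length(is_max)) return(integer(0))
  o <- is_max[order(x[is_max], decreasing = TRUE)]
  taken <- integer(0)
  for (p in o) {
    if (!length(taken) || all(abs(taken - p) > min_dist)) {
      taken <- c(taken, p)
    }
  }
  sort(taken)
}

#' Beat-wise instantaneous heart rate
#'
#' `hr_k = 60000 / nni_k`, assigned at each interval's ending peak. The
#' window mean HR is the mean of `hr_k` for intervals ending inside the span.
#'
#' @param nni An `nni_series`.
#' @param span Length-2 numeric `(start, end)`, seconds, half-open.
#' @return `data.frame` with columns `time` (s) and `hr` (bpm).
#' @export
instantaneous_hr <- function(nni, span) {
  stopifnot(inherits(nni, "nni_series"), length(span) == 2L)
  n_pk <- sum(nni$peak_times >= span[1L] & nni$peak_times < span[2L])
  if (n_pk < 2L) stop("fewer than 2 R-peaks in span")
  in_span <- nni$nni_end_times >= span[1L] & nni$nni_end_times < span[2L]
  if (!any(in_span)) stop("no NN interval ends inside span")
  data.frame(time = nni$nni_end_times[in_span],
             hr = 60000 / nni$nni[in_span])
}

#' Canonical ECG feature names
#' @return Character vector of the 11 ECG feature names in canonical order.
#' @export
ecg_feature_names <- function() {
  c("HRNmean", "HRstd", "HRNFD", "HRNSD", "HRV",
    "HRavNN", "HRsdNN", "HRrMSSD", "HRNN50", "HRpNN50", "HRpNN20")
}

# statistical quartet shared by all channels: normalized mean is handled by
# the caller; here std + normalized first/second differences on a window
# series. Normalization for NFD/NSD is the within-window z-score; a constant
# window (sd = 0) yields NFD = NSD = 0.
stat_diff_features <- function(x) {
  n <- length(x)
  s <- if (n >= 2L) stats::sd(x) else NA_real_
  # relative guard: a window that is constant up to float rounding must not
  # have its representation noise amplified by the z-score
  eps <- 1e-12 * max(1, abs(x))
  if (isTRUE(s > eps)) {
    z <- (x - mean(x)) / s
    nfd <- if (n >= 2L) sum(abs(diff(z, lag = 1L))) / (n - 1L) else NA_real_
    nsd <- if (n >= 3L) sum(abs(diff(z, lag = 2L))) / (n - 2L) else NA_real_
  } else {
    nfd <- if (n >= 2L) 0 else NA_real_
    nsd <- if (n >= 3L) 0 else NA_real_
  }
  c(std = s, NFD = nfd, NSD = nsd)
}

# interval-sequence features (shared with RSP): signed-difference variability
# (as printed, it telescopes), mean, sd, rMSSD and threshold counts.
interval_features <- function(iv, literal_counts = FALSE) {
  n <- length(iv)
  av <- if (n >= 1L) mean(iv) else NA_real_
  sdnn <- if (n >= 2L) stats::sd(iv) else NA_real_
  if (n >= 2L) {
    d <- diff(iv)
    hrv <- sum(d) / n
    rmssd <- sqrt(sum(d^2) / (n - 1L))
    if (literal_counts) {
      nn50 <- sum(iv > 50)
      p50 <- nn50 / n
      p20 <- sum(iv > 20) / n
    } else {
      nn50 <- sum(abs(d) > 50)
      p50 <- nn50 / length(d)
      p20 <- sum(abs(d) > 20) / length(d)
    }
  } else {
    hrv <- rmssd <- nn50 <- p50 <- p20 <- NA_real_
  }
  c(HRV = hrv, avNN = av, sdNN = sdnn, rMSSD = rmssd,
    NN50 = nn50, pNN50 = p50, pNN20 = p20)
}

#' ECG features for one window
#'
#' The 11 time-domain ECG features: normalized mean HR (window-mean HR minus
#' the resting-phase mean), HR standard deviation, normalized first/second
#' differences of the z-scored beat-wise HR series, and the NNI family (the
#' signed-difference variability statistic, avNN, sdNN, rMSSD, NN50, pNN50,
#' pNN20). Difference-based NNI features need at least 3 intervals in the
#' window; otherwise they are returned `NA` with a missing flag.
#'
#' @param nni An `nni_series`.
#' @param window Length-2 numeric `(start, end)`, seconds, half-open.
#' @param baseline An `anx_baseline` providing `hr_rest_mean`.
#' @param literal_counts Use the printed interval-count reading of the
#'   NN50/pNN50/pNN20 formulas instead of the successive-difference count.
#' @return List with `values` (named numeric, `NA` where missing) and
#'   `missing` (named logical).
#' @export
ecg_features <- function(nni, window, baseline, literal_counts = FALSE) {
  stopifnot(inherits(nni, "nni_series"), inherits(baseline, "anx_baseline"))
  in_w <- nni$nni_end_times >= window[1L] & nni$nni_end_times < window[2L]
  iv <- nni$nni[in_w]
  vals <- stats::setNames(rep(NA_real_, 11L), ecg_feature_names())
  if (length(iv) >= 1L) {
    hr <- 60000 / iv
    vals["HRNmean"] <- mean(hr - baseline$hr_rest_mean)
    sdf <- stat_diff_features(hr)
    vals["HRstd"] <- sdf[["std"]]
    vals["HRNFD"] <- sdf[["NFD"]]
    vals["HRNSD"] <- sdf[["NSD"]]
  }
  if (length(iv) >= 3L) {
    ivf <- interval_features(iv, literal_counts = literal_counts)
    vals["HRV"] <- ivf[["HRV"]]
    vals["HRavNN"] <- ivf[["avNN"]]
    vals["HRsdNN"] <- ivf[["sdNN"]]
    vals["HRrMSSD"] <- ivf[["rMSSD"]]
    vals["HRNN50"] <- ivf[["NN50"]]
    vals["HRpNN50"] <- ivf[["pNN50"]]
    vals["HRpNN20"] <- ivf[["pNN20"]]
  }
  list(values = vals, missing = is.na(vals))
}

#' Export detected peaks as a debug CSV
#' @param nni An `nni_series`.
#' @param path Output CSV path (`time_s,nni_ms`; first row has `NA` interval).
#' @return `path`, invisibly.
#' @export
export_peaks_csv <- function(nni, path) {
  iv <- rep(NA_real_, length(nni$peak_times))
  iv[match(nni$nni_end_times, nni$peak_times)] <- nni$nni
  utils::write.csv(data.frame(time_s = nni$peak_times, nni_ms = iv),
                   path, row.names = FALSE)
  invisible(path)
}
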