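#' Canonical feature names
#'
#' Fixed order of the up-to-25 time-domain features: 11 ECG, 7 RSP, 7 EDA.
#'
#' @param channels Subset of `c("ecg", "rsp", "eda")`.
#' @return Character vector of feature names in canonical order.
#' @export
feature_names <- function(channels = c("ecg", "rsp", "eda")) {
  channels <- match.arg(channels, c("ecg", "rsp", "eda"), several.ok = TRUE)
  out <- character(0)
  if ("ecg" %in% channels) out <- c(out, ecg_feature_names())
  if ("rsp" %in% channels) out <- c(out, rsp_feature_names())
  if ("eda" %in% channels) out <- c(out, eda_feature_names())
  out
}

#' The final six-feature set
#'
#' The minimal subset retained by sequential feature selection across the
#' favored models: two ECG and four EDA features.
#'
#' @return Character vector of 6 feature names.
#' @export
final_feature_set <- function() {
  c("HRNmean", "HRstd", "EDANmean", "EDANFD", "EDAnOR", "EDAmmOR")
}

#' Features for a single window
#'
#' The shared feature path: all processing (filtering, peak and response
#' detection) is applied to a bounded slice of each channel ending at the
#' window end, so a feature never depends on samples after the window -- the
#' playback engine and batch extraction call exactly this function and agree
#' bit-exactly.
#'
#' @param records Named list of `biosignal_record`s.
#' @param window Length-2 numeric `(start, end)`, seconds, half-open.
#' @param baseline An `anx_baseline`.
#' @param channels Channels to extract, subset of `c("ecg", "rsp", "eda")`.
#' @param lookback_s Length of the processing slice before the window end,
#'   seconds. Must be at least the window length plus enough context for the
#'   filters and detectors to settle.
#' @return List with `values` (named numeric) and `missing` (named logical),
#'   in canonical feature order.
#' @export
window_features <- function(records, window, baseline,
                            channels = c("ecg", "eda"), lookback_s = 120) {
  channels <- match.arg(channels, c("ecg", "rsp", "eda"), several.ok = TRUE)
  if (lookback_s < window[2L] - window[1L]) {
    stop("lookback_s must cover the window length")
  }
  vals <- numeric(0)
  miss <- logical(0)
  grab <- function(ch) {
    rec <- records[[ch]]
    if (is.null(rec)) stop("channel '", ch, "' missing from records")
    slice_record(rec, max(rec$t0, window[2L] - lookback_s), window[2L])
  }
  if ("ecg" %in% channels) {
    nni <- detect_r_peaks(grab("ecg"))
    f <- ecg_features(nni, window, baseline)
    vals <- c(vals, f$values); miss <- c(miss, f$missing)
  }
  if ("rsp" %in% channels) {
    breaths <- detect_breaths(grab("rsp"))
    f <- rsp_features(breaths, window, baseline)
    vals <- c(vals, f$values); miss <- c(miss, f$missing)
  }
  if ("eda" %in% channels) {
    sl <- grab("eda")
    f <- eda_features(tonic_filter(sl), phasic_filter(sl), window, baseline)
    vals <- c(vals, f$values); miss <- c(miss, f$missing)
  }
  list(values = vals, missing = miss)
}

#' Extract a design matrix from labeled windows
#'
#' One row per window in deterministic order (subject, then window start).
#' Structurally missing features (e.g. mean response magnitude in a window
#' with no orienting response) are imputed as 0 and flagged; the flags are
#' kept beside the matrix, not inside it. Windows that fall outside the
#' recording are dropped with a message.
#'
#' @param subjects A `subject_dataset` or list of them.
#' @param windows Labeled-window `data.frame` (see [label_cohort()]).
#' @param channels Channels to extract.
#' @param baselines Optional named list of `anx_baseline`s keyed by
#'   subject id; computed (full 5-min rest) when omitted.
#' @param lookback_s Processing lookback, seconds.
#' @return Object of class `feature_set`: list with `features`
#'   (`data.frame`, canonical columns), `labels` (factor low/medium/high),
#'   `flags` (logical `data.frame` of imputations) and `windows`
#'   (provenance rows aligned with the matrix).
#' @export
extract_features <- function(subjects, windows, channels = c("ecg", "eda"),
                             baselines = NULL, lookback_s = 120) {
  if (inherits(subjects, "subject_dataset")) subjects <- list(subjects)
  names(subjects) <- vapply(subjects, function(s) s$subject_id, character(1))
  fn <- feature_names(channels)
  windows <- as.data.frame(windows)
  if (!nrow(windows)) {
    empty <- as.data.frame(matrix(numeric(0), 0L, length(fn),
                                  dimnames = list(NULL, fn)))
    return(structure(list(features = empty,
                          labels = factor(character(0),
                                          levels = anx_levels()),
                          flags = empty == 0,
                          windows = windows),
                     class = "feature_set"))
  }
  o <- order(windows$subject_id, windows$session, windows$start)
  windows <- windows[o, , drop = FALSE]
  if (is.null(baselines)) {
    baselines <- lapply(subjects, compute_baseline, rest_span = "full_5min")
  }
  n <- nrow(windows)
  m <- matrix(NA_real_, n, length(fn), dimnames = list(NULL, fn))
  fl <- matrix(FALSE, n, length(fn), dimnames = list(NULL, fn))
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    w <- windows[i, ]
    subj <- subjects[[w$subject_id]]
    recs <- if (identical(w$session, "training")) subj$training$records
            else subj$exposure$records
    rec1 <- recs[[channels[[1L]]]]
    if (w$end > rec1$t0 + record_duration(rec1) + 1e-9 || w$start < rec1$t0) {
      ok[i] <- FALSE
      next
    }
    f <- window_features(recs, c(w$start, w$end),
                         baselines[[w$subject_id]], channels, lookback_s)
    m[i, ] <- f$values
    fl[i, ] <- f$missing
  }
  if (!all(ok)) {
    message(sum(!ok), " window(s) outside the recording were dropped")
    windows <- windows[ok, , drop = FALSE]
    m <- m[ok, , drop = FALSE]
    fl <- fl[ok, , drop = FALSE]
  }
  m[is.na(m)] <- 0  # flagged imputation for classifier-ready rows
  structure(list(features = as.data.frame(m),
                 labels = factor(windows$label, levels = anx_levels()),
                 flags = as.data.frame(fl),
                 windows = windows),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d windows x %d features; labels: %s\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%s=%d", levels(droplevels(x$labels)),
                            table(droplevels(x$labels))), collapse = ", ")))
  invisible(x)
}

#' Write a design matrix as CSV
#' @param fs A `feature_set`.
#' @param path Output CSV path; columns are the canonical feature names plus
#'   `label`.
#' @return `path`, invisibly.
#' @export
export_features_csv <- function(fs, path) {
  df <- cbind(fs$features, label = as.character(fs$labels))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
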