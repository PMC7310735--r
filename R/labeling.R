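#' Labeling configuration
#'
#' One of the ten labeling approaches (five approach families, each with a
#' 10-s and a 60-s window variant) applied for two- or three-level anxiety
#' classes. `SB` uses the subjective arousal ratings; `HR1`/`EDA1` are
#' clip-based (one cohort-level clip ranking); `HR2`/`EDA2` are subject-based
#' (individual clip ranking).
#'
#' @param approach `"SB"`, `"HR1"`, `"HR2"`, `"EDA1"` or `"EDA2"`.
#' @param levels 2 (low/high) or 3 (low/medium/high).
#' @param window_s Feature window length, 10 or 60 seconds.
#' @return Object of class `labeling_config`.
#' @export
labeling_config <- function(approach, levels = 3, window_s = 10) {
  approach <- match.arg(approach, c("SB", "HR1", "HR2", "EDA1", "EDA2"))
  if (!levels %in% c(2, 3)) stop("levels must be 2 or 3")
  if (!window_s %in% c(10, 60)) stop("window_s must be 10 or 60")
  structure(list(approach = approach, levels = as.integer(levels),
                 window_s = as.numeric(window_s)),
            class = "labeling_config")
}

#' @export
print.labeling_config <- function(x, ...) {
  cat(sprintf("<labeling_config> %s, %d levels, %g-s windows\n",
              x$approach, x$levels, x$window_s))
  invisible(x)
}

anx_levels <- function() c("low", "medium", "high")

empty_windows <- function() {
  data.frame(subject_id = character(0), session = character(0),
             start = numeric(0), end = numeric(0), label = character(0),
             clip_index = integer(0), approach = character(0),
             levels = integer(0), window_s = numeric(0))
}

#' Tile labeled segments into windows
#'
#' Non-overlapping windows are tiled from each labeled segment's start; a
#' trailing remainder shorter than `window_s` is discarded. No window ever
#' crosses a segment boundary.
#'
#' @param segments `data.frame` with columns `start`, `end`, `label` and
#'   optionally `session`, `clip_index`.
#' @param window_s Window length, seconds.
#' @return `data.frame` with one row per window (`start`, `end`, `label`,
#'   `session`, `clip_index`).
#' @export
segment_windows <- function(segments, window_s) {
  segments <- as.data.frame(segments)
  if (!nrow(segments)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      label = character(0), session = character(0),
                      clip_index = integer(0)))
  }
  if (is.null(segments$session)) segments$session <- NA_character_
  if (is.null(segments$clip_index)) segments$clip_index <- NA_integer_
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, ]
    k <- floor((s$end - s$start) / window_s + 1e-9)
    if (k < 1L) return(NULL)
    st <- s$start + (seq_len(k) - 1L) * window_s
    data.frame(start = st, end = st + window_s, label = s$label,
               session = s$session, clip_index = s$clip_index)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      label = character(0), session = character(0),
                      clip_index = integer(0)))
  }
  rownames(out) <- NULL
  out
}

# Eq-1/Eq-2 normalized mean of a signal over one clip, per subject.
# hr: mean beat-wise HR over the clip minus the resting mean.
# eda: mean of the range-corrected tonic signal over the clip.
clip_mean_one <- function(subject, signal, clip, baseline, lookback_s = 120) {
  rec <- subject$exposure$records[[if (signal == "hr") "ecg" else "eda"]]
  from <- max(rec$t0, clip$end - lookback_s)
  sl <- slice_record(rec, from, clip$end)
  if (signal == "hr") {
    nni <- detect_r_peaks(sl)
    hr <- tryCatch(instantaneous_hr(nni, c(clip$start, clip$end)),
                   error = function(e) NULL)
    if (is.null(hr)) return(NA_real_)
    mean(hr$hr - baseline$hr_rest_mean)
  } else {
    rng <- baseline$eda_rest_max - baseline$eda_rest_min
    if (!is.finite(rng) || rng <= 0) return(NA_real_)
    tw <- slice_record(tonic_filter(sl), clip$start, clip$end)
    if (!length(tw$samples)) return(NA_real_)
    mean((tw$samples - baseline$eda_rest_min) / rng)
  }
}

# per-subject 16-vector of normalized clip means
subject_clip_means <- function(subject, signal, baseline = NULL,
                               lookback_s = 120) {
  signal <- match.arg(signal, c("hr", "eda"))
  if (is.null(baseline)) baseline <- compute_baseline(subject, "full_5min")
  clips <- layout_segments(subject$exposure$layout, "clip")
  out <- rep(NA_real_, 16L)
  for (i in seq_len(nrow(clips))) {
    ci <- clips$clip_index[i]
    out[ci] <- clip_mean_one(subject, signal, clips[i, ], baseline,
                             lookback_s)
  }
  out
}

#' Cohort-mean normalized clip means
#'
#' Per subject and clip, the mean of the baseline-normalized signal over the
#' clip (normalized mean HR or range-corrected EDA), then averaged across
#' subjects. Subjects missing a clip are dropped from that clip's average
#' with a message.
#'
#' @param cohort List of `subject_dataset`s (at least one with a complete
#'   exposure session).
#' @param signal `"hr"` or `"eda"`.
#' @param baselines Optional list of `anx_baseline`s matching `cohort`;
#'   computed (full 5-min rest) when omitted.
#' @param lookback_s Processing lookback per clip, seconds.
#' @return Numeric 16-vector, one cohort-mean value per clip index.
#' @export
clip_signal_means <- function(cohort, signal, baselines = NULL,
                              lookback_s = 120) {
  signal <- match.arg(signal, c("hr", "eda"))
  stopifnot(length(cohort) >= 1L)
  m <- vapply(seq_along(cohort), function(i) {
    b <- if (!is.null(baselines)) baselines[[i]] else NULL
    subject_clip_means(cohort[[i]], signal, b, lookback_s)
  }, numeric(16L))
  m <- matrix(m, nrow = 16L)
  if (anyNA(m)) {
    message(sum(is.na(m)), " missing subject-clip means averaged over the ",
            "remaining subjects")
  }
  rowMeans(m, na.rm = TRUE)
}

# rank clips by decreasing mean, ties broken by ascending clip index
rank_clips <- function(means) {
  if (anyNA(means)) stop("clip ranking needs all 16 clip means")
  order(-means, seq_along(means))
}

rest_low_segment <- function(subject, span = c("last_3min", "full_5min")) {
  span <- match.arg(span)
  rest <- layout_segments(subject$training$layout, "rest")[1L, ]
  if (span == "last_3min") {
    data.frame(start = rest$end - 180, end = rest$end, label = "low",
               session = "training", clip_index = NA_integer_)
  } else {
    data.frame(start = rest$start, end = rest$start + 300, label = "low",
               session = "training", clip_index = NA_integer_)
  }
}

finalize_windows <- function(win, subject_id, config) {
  if (!nrow(win)) return(empty_windows())
  if (config$levels == 2L) {
    win <- win[win$label != "medium", , drop = FALSE]
  }
  if (!nrow(win)) return(empty_windows())
  data.frame(subject_id = subject_id, session = win$session,
             start = win$start, end = win$end, label = win$label,
             clip_index = win$clip_index, approach = config$approach,
             levels = config$levels, window_s = config$window_s,
             row.names = NULL)
}

clip_segments_with_labels <- function(subject, label_by_clip) {
  clips <- layout_segments(subject$exposure$layout, "clip")
  lab <- label_by_clip[clips$clip_index]
  keep <- !is.na(lab)
  data.frame(start = clips$start[keep], end = clips$end[keep],
             label = lab[keep], session = "exposure",
             clip_index = clips$clip_index[keep])
}

#' Clip-based labeling (HR1/EDA1)
#'
#' One cohort-level clip ranking: the three clips with the highest cohort
#' mean are 'high'; the three mid-ranked clips (ranks 7--9 of 16) are
#' 'medium'; 'low' is the last 3 minutes of the training rest. The same
#' clip-label map applies to every subject. Balanced by construction
#' (3 + 3 + 3 labeled minutes per subject).
#'
#' @param cohort List of `subject_dataset`s.
#' @param config A `labeling_config` with approach `HR1` or `EDA1`.
#' @param baselines Optional list of `anx_baseline`s matching `cohort`.
#' @param lookback_s Processing lookback, seconds.
#' @return `data.frame` of labeled windows over all subjects.
#' @export
clip_based_labels <- function(cohort, config, baselines = NULL,
                              lookback_s = 120) {
  stopifnot(inherits(config, "labeling_config"))
  if (!config$approach %in% c("HR1", "EDA1")) {
    stop("clip_based_labels needs approach HR1 or EDA1")
  }
  signal <- if (config$approach == "HR1") "hr" else "eda"
  means <- clip_signal_means(cohort, signal, baselines, lookback_s)
  rk <- rank_clips(means)
  label_by_clip <- rep(NA_character_, 16L)
  label_by_clip[rk[1:3]] <- "high"
  label_by_clip[rk[7:9]] <- "medium"
  out <- lapply(cohort, function(subj) {
    seg <- rbind(clip_segments_with_labels(subj, label_by_clip),
                 rest_low_segment(subj, "last_3min"))
    finalize_windows(segment_windows(seg, config$window_s),
                     subj$subject_id, config)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "label_by_clip") <- label_by_clip
  res
}

#' Subject-based labeling (HR2/EDA2)
#'
#' Individual clip ranking per subject: the 8 clips with the highest
#' individual normalized mean are 'high', the remaining 8 'medium'; 'low' is
#' the entire 5-minute training rest. Three-level class shares are therefore
#' 8/21, 8/21 and 5/21 of labeled minutes (38%/38%/24%).
#'
#' @param subject A `subject_dataset` with a complete 16-clip exposure.
#' @param config A `labeling_config` with approach `HR2` or `EDA2`.
#' @param baseline Optional `anx_baseline` (full 5-min rest if omitted).
#' @param lookback_s Processing lookback, seconds.
#' @return `data.frame` of labeled windows for the subject, with the
#'   clip-label map in attribute `label_by_clip`.
#' @export
subject_based_labels <- function(subject, config, baseline = NULL,
                                 lookback_s = 120) {
  stopifnot(inherits(config, "labeling_config"))
  if (!config$approach %in% c("HR2", "EDA2")) {
    stop("subject_based_labels needs approach HR2 or EDA2")
  }
  clips <- layout_segments(subject$exposure$layout, "clip")
  if (nrow(clips) != 16L) {
    stop("subject-based split undefined: exposure has ", nrow(clips),
         " clips, needs 16")
  }
  signal <- if (config$approach == "HR2") "hr" else "eda"
  means <- subject_clip_means(subject, signal, baseline, lookback_s)
  rk <- rank_clips(means)
  label_by_clip <- rep("medium", 16L)
  label_by_clip[rk[1:8]] <- "high"
  seg <- rbind(clip_segments_with_labels(subject, label_by_clip),
               rest_low_segment(subject, "full_5min"))
  res <- finalize_windows(segment_windows(seg, config$window_s),
                          subject$subject_id, config)
  attr(res, "label_by_clip") <- label_by_clip
  res
}

#' Subjective labeling (SB)
#'
#' Uses the four arousal ratings collected after every fourth clip: only the
#' clip right before each rating is labeled, 'high' for ratings 3--4 and
#' 'medium' for ratings 1--2; 'low' is the last 3 minutes of the training
#' rest. A missing rating leaves that clip unlabeled (message).
#'
#' @param subject A `subject_dataset`.
#' @param config A `labeling_config` with approach `SB`.
#' @return `data.frame` of labeled windows for the subject.
#' @export
subjective_labels <- function(subject, config) {
  stopifnot(inherits(config, "labeling_config"))
  if (config$approach != "SB") stop("subjective_labels needs approach SB")
  ratings <- subject$exposure$layout$ratings
  if (nrow(ratings) < 4L) {
    message(subject$subject_id, ": only ", nrow(ratings),
            " of 4 ratings present; unrated clips stay unlabeled")
  }
  label_by_clip <- rep(NA_character_, 16L)
  if (nrow(ratings)) {
    label_by_clip[ratings$after_clip_index] <-
      ifelse(ratings$value >= 3, "high", "medium")
  }
  seg <- rbind(clip_segments_with_labels(subject, label_by_clip),
               rest_low_segment(subject, "last_3min"))
  finalize_windows(segment_windows(seg, config$window_s),
                   subject$subject_id, config)
}

#' Labeled windows for any approach
#'
#' Dispatch helper: applies the configured labeling approach to a cohort and
#' returns one labeled-window table.
#'
#' @param cohort List of `subject_dataset`s.
#' @param config A `labeling_config`.
#' @param baselines Optional list of `anx_baseline`s matching `cohort`.
#' @param lookback_s Processing lookback, seconds.
#' @return `data.frame` of labeled windows over all subjects.
#' @export
label_cohort <- function(cohort, config, baselines = NULL, lookback_s = 120) {
  stopifnot(inherits(config, "labeling_config"))
  if (config$approach %in% c("HR1", "EDA1")) {
    return(clip_based_labels(cohort, config, baselines, lookback_s))
  }
  out <- lapply(seq_along(cohort), function(i) {
    b <- if (!is.null(baselines)) baselines[[i]] else NULL
    if (config$approach == "SB") {
      subjective_labels(cohort[[i]], config)
    } else {
      subject_based_labels(cohort[[i]], config, b, lookback_s)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
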