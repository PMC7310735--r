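#' Playback a session with on-line prediction
#'
#' Emulates real-time acquisition: after a warm-up of one update interval, a
#' prediction is emitted every `update_s` seconds from the features of the
#' immediately preceding window. Features are computed by the same
#' [window_features()] path as batch extraction, whose processing slice ends
#' at the emit time, so no event ever depends on samples after it and
#' off-line extraction on the same windows agrees bit-exactly.
#'
#' An event carries a true label only when its full window lies inside one
#' labeled segment; windows straddling a label boundary count as unlabeled.
#'
#' @param records Named list of `biosignal_record`s for the session.
#' @param model An `anx_model`.
#' @param baseline The subject's `anx_baseline` (required: normalized
#'   features are undefined without it).
#' @param update_s Update interval, seconds (default 10).
#' @param labels Optional labeled-window or labeled-segment `data.frame`
#'   with columns `start`, `end`, `label` (and optionally `session`,
#'   filtered by `session_kind`).
#' @param session_kind Which session the records belong to, used to filter
#'   `labels`.
#' @param channels Channels the model needs.
#' @param lookback_s Processing lookback, seconds.
#' @return `data.frame` of prediction events: `emit_time`, `start`, `end`,
#'   `predicted`, one score column per class, `true_label` (`NA` when
#'   unlabeled).
#' @export
playback <- function(records, model, baseline, update_s = 10, labels = NULL,
                     session_kind = "exposure", channels = c("ecg", "eda"),
                     lookback_s = 120) {
  if (missing(baseline) || is.null(baseline)) {
    stop("playback needs a baseline: normalized features are undefined")
  }
  stopifnot(inherits(model, "anx_model"))
  for (ch in channels) {
    if (is.null(records[[ch]])) {
      stop("model requires channel '", ch, "' which is not in the session")
    }
  }
  rec1 <- records[[channels[[1L]]]]
  t_start <- rec1$t0
  t_end <- rec1$t0 + record_duration(rec1)
  emit <- seq(t_start + update_s, t_end + 1e-9, by = update_s)
  if (!is.null(labels)) {
    labels <- as.data.frame(labels)
    if (!is.null(labels$session)) {
      labels <- labels[labels$session == session_kind, , drop = FALSE]
    }
  }
  rows <- lapply(emit, function(tt) {
    w <- c(tt - update_s, tt)
    f <- window_features(records, w, baseline, channels, lookback_s)
    vals <- f$values
    vals[is.na(vals)] <- 0
    nd <- as.data.frame(as.list(vals))
    pred <- predict(model, nd, type = "class")
    sc <- predict(model, nd, type = "prob")
    true_label <- NA_character_
    if (!is.null(labels) && nrow(labels)) {
      inside <- labels$start <= w[1L] + 1e-9 & labels$end >= w[2L] - 1e-9
      if (any(inside)) true_label <- labels$label[which(inside)[1L]]
    }
    out <- data.frame(emit_time = tt, start = w[1L], end = w[2L],
                      predicted = as.character(pred),
                      true_label = true_label)
    for (cls in colnames(sc)) out[[paste0("score_", cls)]] <- sc[1L, cls]
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' On-line agreement with the true labels
#'
#' The fraction of correct predictions among events whose window lies inside
#' a labeled segment; events without a true class are excluded from the
#' denominator. `NA` when no event is labeled.
#'
#' @param events Output of [playback()].
#' @return Numeric fraction, or `NA_real_`.
#' @export
playback_accuracy <- function(events) {
  lab <- !is.na(events$true_label)
  if (!any(lab)) return(NA_real_)
  mean(events$predicted[lab] == events$true_label[lab])
}
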