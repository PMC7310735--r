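#' Construct a biosignal record
#'
#' One uniformly sampled channel of a session: ECG (arbitrary voltage units),
#' EDA (microsiemens) or RSP (chest displacement, percent).
#'
#' @param channel One of `"ecg"`, `"eda"`, `"rsp"`.
#' @param samples Numeric vector of samples.
#' @param sampling_rate Sampling rate in Hz (default 100, the wearable
#'   device's per-channel rate).
#' @param t0 Time offset of the first sample within the session, seconds.
#' @return An object of class `biosignal_record`.
#' @export
biosignal_record <- function(channel, samples, sampling_rate = 100, t0 = 0) {
  channel <- match.arg(channel, c("ecg", "eda", "rsp"))
  stopifnot(is.numeric(samples), is.numeric(sampling_rate),
            length(sampling_rate) == 1L, sampling_rate > 0,
            is.numeric(t0), length(t0) == 1L)
  structure(
    list(channel = channel, samples = as.numeric(samples),
         sampling_rate = as.numeric(sampling_rate), t0 = as.numeric(t0)),
    class = "biosignal_record"
  )
}

#' @export
print.biosignal_record <- function(x, ...) {
  cat(sprintf("<biosignal_record> channel=%s  n=%d  rate=%g Hz  t0=%g s  duration=%.1f s\n",
              x$channel, length(x$samples), x$sampling_rate, x$t0,
              record_duration(x)))
  invisible(x)
}

#' Duration of a record in seconds
#' @param record A `biosignal_record`.
#' @return Duration `length(samples)/sampling_rate`, seconds.
#' @export
record_duration <- function(record) {
  length(record$samples) / record$sampling_rate
}

#' Sample times of a record
#' @param record A `biosignal_record`.
#' @return Numeric vector of sample times (seconds, session clock).
#' @export
record_times <- function(record) {
  record$t0 + (seq_along(record$samples) - 1L) / record$sampling_rate
}

#' Slice a record to a time span
#'
#' Half-open span `[from, to)` on the session clock. Used internally to bound
#' the samples a feature window may see.
#'
#' @param record A `biosignal_record`.
#' @param from,to Span bounds, seconds.
#' @return A `biosignal_record` covering the overlap of the span and the
#'   record; `t0` adjusted accordingly.
#' @export
slice_record <- function(record, from, to) {
  fs <- record$sampling_rate
  n <- length(record$samples)
  i0 <- max(1L, as.integer(ceiling((from - record$t0) * fs - 1e-9)) + 1L)
  i1 <- min(n, as.integer(ceiling((to - record$t0) * fs - 1e-9)))
  if (i1 < i0) {
    return(biosignal_record(record$channel, numeric(0), fs, from))
  }
  biosignal_record(record$channel, record$samples[i0:i1], fs,
                   record$t0 + (i0 - 1L) / fs)
}

#' Construct a session layout
#'
#' Timed segments and rating events of one session. Time coordinates are
#' seconds from session start; segments are half-open `[start, end)`,
#' non-overlapping and time-ordered. A complete exposure session holds a
#' 1-minute demo clip, 16 one-minute video clips with a 4-point arousal
#' rating after every 4th clip, and a final 5-minute rest.
#'
#' @param session_kind `"training"` or `"exposure"`.
#' @param segments `data.frame` with columns `role` ("rest"/"demo"/"clip"),
#'   `clip_index` (1..16 for clips, `NA` otherwise), `start`, `end` (seconds).
#' @param ratings `data.frame` with columns `time` (seconds),
#'   `after_clip_index`, `value` (integer 1..4); may be empty.
#' @return An object of class `session_layout`.
#' @export
session_layout <- function(session_kind, segments,
                           ratings = data.frame(time = numeric(0),
                                                after_clip_index = integer(0),
                                                value = integer(0))) {
  session_kind <- match.arg(session_kind, c("training", "exposure"))
  segments <- as.data.frame(segments)
  ratings <- as.data.frame(ratings)
  required <- c("role", "clip_index", "start", "end")
  if (!all(required %in% names(segments))) {
    stop("segments must have columns: ", paste(required, collapse = ", "))
  }
  if (!all(segments$role %in% c("rest", "demo", "clip"))) {
    stop("segment roles must be rest/demo/clip")
  }
  if (any(segments$end <= segments$start)) {
    stop("segment end must exceed start")
  }
  o <- order(segments$start)
  segments <- segments[o, , drop = FALSE]
  rownames(segments) <- NULL
  if (nrow(segments) > 1L &&
      any(segments$start[-1L] < segments$end[-nrow(segments)] - 1e-9)) {
    stop("segments overlap: layout invalid")
  }
  is_clip <- segments$role == "clip"
  if (any(is.na(segments$clip_index[is_clip]))) {
    stop("clip segments need a clip_index")
  }
  if (nrow(ratings) && !all(ratings$value %in% 1:4)) {
    stop("rating values must be integers in 1..4")
  }
  structure(
    list(session_kind = session_kind, segments = segments, ratings = ratings),
    class = "session_layout"
  )
}

#' @export
print.session_layout <- function(x, ...) {
  cat(sprintf("<session_layout> %s: %d segments (%d clips), %d ratings, span [%g, %g) s\n",
              x$session_kind, nrow(x$segments),
              sum(x$segments$role == "clip"), nrow(x$ratings),
              min(x$segments$start), max(x$segments$end)))
  invisible(x)
}

#' Segments of a layout by role
#' @param layout A `session_layout`.
#' @param role Segment role to keep.
#' @return Subset of the segments data.frame.
#' @export
layout_segments <- function(layout, role = NULL) {
  seg <- layout$segments
  if (!is.null(role)) seg <- seg[seg$role %in% role, , drop = FALSE]
  seg
}

#' Construct a subject dataset
#'
#' Pairs one subject's biofeedback training session (carrying the 5-minute
#' rest used for baselines) with their exposure session. Both sessions must
#' carry ECG and EDA; RSP is optional (the final models exclude it).
#'
#' @param subject_id Character id.
#' @param training,exposure Each a list with elements `layout`
#'   (`session_layout`) and `records` (named list of `biosignal_record`s).
#' @return An object of class `subject_dataset`.
#' @export
subject_dataset <- function(subject_id, training, exposure) {
  for (s in list(training, exposure)) {
    stopifnot(inherits(s$layout, "session_layout"), is.list(s$records))
    missing_ch <- setdiff(c("ecg", "eda"), names(s$records))
    if (length(missing_ch)) {
      stop("session is missing required channel(s): ",
           paste(missing_ch, collapse = ", "))
    }
  }
  if (training$layout$session_kind != "training" ||
      exposure$layout$session_kind != "exposure") {
    stop("session kinds do not match slots")
  }
  structure(list(subject_id = as.character(subject_id),
                 training = training, exposure = exposure),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("<subject_dataset> %s: training channels {%s}, exposure channels {%s}\n",
              x$subject_id,
              paste(names(x$training$records), collapse = ","),
              paste(names(x$exposure$records), collapse = ",")))
  invisible(x)
}

# ---- I/O: CSV dialect + JSON sidecar -----------------------------------

layout_to_list <- function(layout) {
  list(session_kind = layout$session_kind,
       segments = layout$segments,
       ratings = layout$ratings)
}

layout_from_list <- function(x) {
  seg <- as.data.frame(x$segments)
  if (!nrow(seg)) stop("metadata holds no segments")
  if (is.null(seg$clip_index)) seg$clip_index <- NA_integer_
  rat <- if (!is.null(x$ratings) && length(x$ratings)) {
    as.data.frame(x$ratings)
  } else {
    data.frame(time = numeric(0), after_clip_index = integer(0),
               value = integer(0))
  }
  session_layout(x$session_kind, seg, rat)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write a session to disk
#'
#' Writes a CSV signal file (header `t,ecg,eda,rsp` restricted to the
#' channels present; one row per sample tick; full `%.17g` precision so the
#' round trip is bit-exact) and a JSON metadata sidecar next to it.
#'
#' @param layout A `session_layout`.
#' @param records Named list of `biosignal_record`s (non-empty).
#' @param path CSV file path; the sidecar is written at the same path with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_session <- function(layout, records, path) {
  if (!length(records)) stop("empty channel map: nothing to write")
  stopifnot(inherits(layout, "session_layout"))
  rates <- vapply(records, function(r) r$sampling_rate, numeric(1))
  if (length(unique(rates)) != 1L) {
    stop("all channels must share one sampling rate for the CSV dialect")
  }
  ns <- vapply(records, function(r) length(r$samples), integer(1))
  n <- max(ns)
  fs <- rates[[1L]]
  t0 <- records[[1L]]$t0
  cols <- list(t = sprintf("%.17g", t0 + (seq_len(n) - 1L) / fs))
  for (ch in intersect(c("ecg", "eda", "rsp"), names(records))) {
    v <- records[[ch]]$samples
    length(v) <- n  # pad with NA if ragged
    cols[[ch]] <- sprintf("%.17g", v)
  }
  dt <- data.table::as.data.table(cols)
  tryCatch(
    data.table::fwrite(dt, path, quote = FALSE),
    error = function(e) stop("failed writing signal file '", path, "': ",
                             conditionMessage(e))
  )
  meta <- c(layout_to_list(layout),
            list(sampling_rate = fs, t0 = t0,
                 channels = setdiff(names(cols), "t")))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a session from disk
#'
#' Reads either the package's CSV dialect (header `t,ecg,eda,rsp`, JSON
#' sidecar) or an OpenSignals-style text file (`#`-prefixed JSON header,
#' whitespace-separated columns) with the same sidecar. Validates every
#' layout invariant. If the signal file declares a sampling rate that
#' differs from the sidecar's, channels are linearly resampled to the
#' sidecar rate.
#'
#' @param path Signal file path (sidecar expected at the `.json` sibling).
#' @return List with elements `layout` and `records`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no signal file at '", path, "'")
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("no metadata sidecar at '", sp, "'")
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  layout <- layout_from_list(meta)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    rec <- read_opensignals(path)
  } else if (grepl("^t[,;]", first)) {
    dt <- data.table::fread(path, sep = ",", header = TRUE)
    chans <- setdiff(names(dt), "t")
    t0 <- dt$t[1L]
    fs <- if (nrow(dt) > 1L) 1 / (dt$t[2L] - dt$t[1L]) else meta$sampling_rate
    rec <- lapply(chans, function(ch) {
      biosignal_record(ch, dt[[ch]], sampling_rate = fs, t0 = t0)
    })
    names(rec) <- chans
  } else {
    stop("unknown signal file dialect in '", path, "'")
  }
  want <- meta$channels
  missing_ch <- setdiff(want, names(rec))
  if (length(missing_ch)) {
    stop("signal file is missing channel(s): ",
         paste(missing_ch, collapse = ", "))
  }
  rec <- rec[want]
  rec <- lapply(rec, function(r) {
    if (abs(r$sampling_rate - meta$sampling_rate) > 1e-9) {
      resample_record(r, meta$sampling_rate)
    } else r
  })
  list(layout = layout, records = rec)
}

resample_record <- function(record, new_rate) {
  old_t <- record_times(record)
  dur <- record_duration(record)
  new_n <- max(1L, floor(dur * new_rate))
  new_t <- record$t0 + (seq_len(new_n) - 1L) / new_rate
  y <- stats::approx(old_t, record$samples, xout = new_t, rule = 2)$y
  biosignal_record(record$channel, y, new_rate, record$t0)
}

#' Read an OpenSignals-style text file
#'
#' Expects `#`-prefixed header lines, one of which is a JSON object carrying
#' `"sampling rate"` and `"column"` labels, followed by whitespace-separated
#' sample columns. Column labels containing `ecg`/`eda`/`rsp`
#' (case-insensitive) are mapped to those channels; other columns dropped.
#'
#' @param path File path.
#' @return Named list of `biosignal_record`s.
#' @export
read_opensignals <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  js <- NULL
  for (h in hdr) {
    raw <- sub("^#+\\s*", "", h)
    parsed <- tryCatch(jsonlite::fromJSON(raw), error = function(e) NULL)
    if (is.list(parsed)) { js <- parsed; break }
  }
  if (is.null(js)) stop("no JSON header found in OpenSignals file '", path, "'")
  dev <- if (!is.null(js$`sampling rate`)) js else js[[1L]]
  fs <- dev$`sampling rate`
  cols <- unlist(dev$column)
  if (is.null(fs) || is.null(cols)) {
    stop("OpenSignals header lacks 'sampling rate' or 'column' in '",
         path, "'")
  }
  mat <- utils::read.table(text = body)
  if (ncol(mat) != length(cols)) {
    stop("OpenSignals column count mismatch in '", path, "'")
  }
  out <- list()
  for (ch in c("ecg", "eda", "rsp")) {
    j <- grep(ch, cols, ignore.case = TRUE)
    if (length(j) == 1L) {
      out[[ch]] <- biosignal_record(ch, mat[[j]], sampling_rate = fs, t0 = 0)
    }
  }
  if (!length(out)) stop("no ecg/eda/rsp columns found in '", path, "'")
  out
}

# ---- Baseline ----------------------------------------------------------

#' Compute a subject's resting-phase baseline
#'
#' Summarizes the resting phase of the biofeedback training session: mean
#' heart rate and mean breathing rate over the span, and the extrema of the
#' low-pass-filtered EDA used by the Lykken range correction. The span is
#' either the full 5-minute rest or its last 3 minutes.
#'
#' @param subject A `subject_dataset`.
#' @param rest_span `"full_5min"` or `"last_3min"`.
#' @return An object of class `anx_baseline` with fields `subject_id`,
#'   `hr_rest_mean` (bpm), `br_rest_mean` (breaths/min, `NA` without RSP),
#'   `eda_rest_min`, `eda_rest_max` (uS), `rest_window`.
#' @export
compute_baseline <- function(subject, rest_span = c("full_5min", "last_3min")) {
  rest_span <- match.arg(rest_span)
  rest <- layout_segments(subject$training$layout, "rest")
  if (!nrow(rest)) stop("training session has no rest segment")
  rest <- rest[1L, ]
  need <- if (rest_span == "full_5min") 300 else 180
  if (rest$end - rest$start < need - 1e-9) {
    stop(sprintf("rest segment is %.0f s; %s needs %d s",
                 rest$end - rest$start, rest_span, need))
  }
  span <- if (rest_span == "full_5min") {
    c(rest$start, rest$start + 300)
  } else {
    c(rest$end - 180, rest$end)
  }
  ecg <- slice_record(subject$training$records$ecg, span[1L], span[2L])
  nni <- detect_r_peaks(ecg)
  if (length(nni$nni) < 2L) {
    stop("no usable R-peaks detected in the rest span")
  }
  hr <- instantaneous_hr(nni, span)
  eda <- slice_record(subject$training$records$eda, span[1L], span[2L])
  tonic <- tonic_filter(eda)
  br <- NA_real_
  if (!is.null(subject$training$records$rsp)) {
    rsp <- slice_record(subject$training$records$rsp, span[1L], span[2L])
    breaths <- detect_breaths(rsp)
    n_pk <- sum(breaths$breath_peak_times >= span[1L] &
                  breaths$breath_peak_times < span[2L])
    br <- 60 * n_pk / (span[2L] - span[1L])
  }
  structure(
    list(subject_id = subject$subject_id,
         hr_rest_mean = mean(hr$hr),
         br_rest_mean = br,
         eda_rest_min = min(tonic$samples),
         eda_rest_max = max(tonic$samples),
         rest_window = span),
    class = "anx_baseline"
  )
}

#' @export
print.anx_baseline <- function(x, ...) {
  cat(sprintf("<anx_baseline> %s: HR %.1f bpm, BR %s /min, EDA [%.3f, %.3f] uS, rest [%g, %g) s\n",
              x$subject_id, x$hr_rest_mean,
              ifelse(is.na(x$br_rest_mean), "NA",
                     sprintf("%.1f", x$br_rest_mean)),
              x$eda_rest_min, x$eda_rest_max,
              x$rest_window[1L], x$rest_window[2L]))
  invisible(x)
}
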