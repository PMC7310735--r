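#' Simulation configuration
#'
#' Parameters of the synthetic arousal-session simulator. It emulates the
#' study structure: a training session holding a 5-minute rest, and an
#' exposure session of a 1-minute demo clip plus 16 one-minute video clips
#' with a 4-point arousal rating after every fourth clip and a final
#' 5-minute rest. Each clip carries a latent arousal level (0 calm,
#' 1 medium, 2 high) that raises heart rate, shrinks RR variability, raises
#' the skin-conductance-response rate and the breathing rate, and drives the
#' ratings.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed; fully determines the cohort.
#' @param rest_hr Resting heart rate, bpm.
#' @param hr_arousal_delta HR elevation per arousal level, bpm.
#' @param hrv_rest Stationary SD of the RR jitter at rest, ms.
#' @param hrv_arousal_shrink Multiplicative RR-variability shrink per level.
#' @param scr_rate_rest,scr_rate_high SCR event rates at arousal 0 and 2,
#'   events/min (linear in between).
#' @param scr_amp_range SCR amplitude range, uS.
#' @param tonic_level Tonic EDA level, uS.
#' @param tonic_drift Tonic drift, uS/min.
#' @param tonic_arousal_gain Tonic elevation per arousal level, uS.
#' @param br_rest Resting breathing rate, breaths/min.
#' @param br_arousal_delta BR elevation per arousal level, breaths/min.
#' @param arousal_clip_assignment Latent arousal per clip: a 16-vector used
#'   for every subject, an `n_subjects x 16` matrix, or `NULL` for the
#'   default multiset (5 high, 6 medium, 5 calm) permuted per subject.
#' @param rating_noise Probability that a rating deviates by 1 from the
#'   latent value.
#' @param noise_sd Named sensor-noise SDs for `ecg`, `eda`, `rsp`.
#' @param sampling_rate Hz.
#' @param include_rsp Emit the RSP channel.
#' @param ar_phi AR(1) coefficient of the RR jitter.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 1, seed = 1,
                              rest_hr = 70, hr_arousal_delta = 5,
                              hrv_rest = 40, hrv_arousal_shrink = 0.8,
                              scr_rate_rest = 2, scr_rate_high = 6,
                              scr_amp_range = c(0.1, 0.6),
                              tonic_level = 2, tonic_drift = 0.02,
                              tonic_arousal_gain = 0.25,
                              br_rest = 14, br_arousal_delta = 2,
                              arousal_clip_assignment = NULL,
                              rating_noise = 0.1,
                              noise_sd = c(ecg = 0.03, eda = 0.01, rsp = 1),
                              sampling_rate = 100, include_rsp = TRUE,
                              ar_phi = 0.8) {
  stopifnot(n_subjects >= 1, rest_hr > 0, hrv_rest >= 0,
            hrv_arousal_shrink > 0, scr_rate_rest >= 0, scr_rate_high >= 0,
            length(scr_amp_range) == 2L, scr_amp_range[1L] > 0,
            br_rest > 0, rating_noise >= 0, rating_noise <= 1,
            sampling_rate > 0, ar_phi >= 0, ar_phi < 1)
  if (!is.null(arousal_clip_assignment)) {
    a <- arousal_clip_assignment
    if (is.matrix(a)) {
      stopifnot(ncol(a) == 16L, nrow(a) == n_subjects)
    } else {
      stopifnot(length(a) == 16L)
    }
    stopifnot(all(a %in% 0:2))
  }
  structure(list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    rest_hr = rest_hr, hr_arousal_delta = hr_arousal_delta,
    hrv_rest = hrv_rest, hrv_arousal_shrink = hrv_arousal_shrink,
    scr_rate_rest = scr_rate_rest, scr_rate_high = scr_rate_high,
    scr_amp_range = scr_amp_range, tonic_level = tonic_level,
    tonic_drift = tonic_drift, tonic_arousal_gain = tonic_arousal_gain,
    br_rest = br_rest, br_arousal_delta = br_arousal_delta,
    arousal_clip_assignment = arousal_clip_assignment,
    rating_noise = rating_noise, noise_sd = noise_sd,
    sampling_rate = sampling_rate, include_rsp = include_rsp,
    ar_phi = ar_phi), class = "simulation_config")
}

#' Strong-effect preset
#'
#' High-arousal clips elevated by 15 bpm (7.5 bpm per level), SCR rate four
#' times the resting rate at high arousal, noiseless ratings.
#'
#' @param n_subjects,seed Passed through.
#' @param ... Further overrides for [simulation_config()].
#' @return A `simulation_config`.
#' @export
simulation_config_strong <- function(n_subjects = 40, seed = 1, ...) {
  simulation_config(n_subjects = n_subjects, seed = seed,
                    hr_arousal_delta = 7.5,
                    scr_rate_rest = 2, scr_rate_high = 8,
                    rating_noise = 0, ...)
}

#' Null-effect preset
#'
#' No arousal effect on any signal (and no tonic drift, so no nuisance
#' separability between the training rest and the exposure clips); labels
#' still exist via the latent assignment, making this the chance-level
#' control.
#'
#' @param n_subjects,seed Passed through.
#' @param ... Further overrides for [simulation_config()].
#' @return A `simulation_config`.
#' @export
simulation_config_null <- function(n_subjects = 20, seed = 1, ...) {
  simulation_config(n_subjects = n_subjects, seed = seed,
                    hr_arousal_delta = 0, hrv_arousal_shrink = 1,
                    scr_rate_rest = 2, scr_rate_high = 2,
                    tonic_drift = 0, tonic_arousal_gain = 0,
                    br_arousal_delta = 0, rating_noise = 0, ...)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config> n=%d seed=%d | HR %g+%g bpm/level,",
                     " RR sd %g ms x%g/level | SCR %g-%g /min, amp [%g,%g] uS",
                     " | BR %g+%g /min\n"),
              x$n_subjects, x$seed, x$rest_hr, x$hr_arousal_delta,
              x$hrv_rest, x$hrv_arousal_shrink, x$scr_rate_rest,
              x$scr_rate_high, x$scr_amp_range[1L], x$scr_amp_range[2L],
              x$br_rest, x$br_arousal_delta))
  invisible(x)
}

# ---- session timelines --------------------------------------------------

training_layout <- function() {
  session_layout("training",
                 data.frame(role = "rest", clip_index = NA_integer_,
                            start = 0, end = 300))
}

exposure_layout <- function(ratings_df) {
  t <- 0
  rows <- list(data.frame(role = "demo", clip_index = NA_integer_,
                          start = 0, end = 60))
  t <- 60
  for (i in 1:16) {
    rows[[length(rows) + 1L]] <- data.frame(role = "clip", clip_index = i,
                                            start = t, end = t + 60)
    t <- t + 60
    if (i %% 4L == 0L) t <- t + 20  # rating pause
  }
  rows[[length(rows) + 1L]] <- data.frame(role = "rest",
                                          clip_index = NA_integer_,
                                          start = t, end = t + 300)
  session_layout("exposure", do.call(rbind, rows), ratings_df)
}

# per-segment arousal timeline for a layout (data.frame: start, end, arousal)
arousal_timeline <- function(layout, clip_arousal) {
  seg <- layout$segments
  a <- ifelse(seg$role == "clip", clip_arousal[seg$clip_index], 0)
  # close the inter-segment pauses with arousal 0 so the timeline is
  # contiguous over [0, end of last segment]
  out <- data.frame(start = seg$start, end = seg$end, arousal = a)
  gaps <- which(out$start[-1L] > out$end[-nrow(out)] + 1e-9)
  if (length(gaps)) {
    fill <- data.frame(start = out$end[gaps], end = out$start[gaps + 1L],
                       arousal = 0)
    out <- rbind(out, fill)
    out <- out[order(out$start), ]
  }
  rownames(out) <- NULL
  out
}

arousal_at <- function(timeline, t) {
  i <- findInterval(t, timeline$start)
  ifelse(i >= 1L & t < timeline$end[pmax(i, 1L)], timeline$arousal[pmax(i, 1L)], 0)
}

# ---- channel renderers --------------------------------------------------

# beat instants from an AR(1)-jittered RR process with arousal-dependent
# mean and variability
gen_beats <- function(timeline, cfg) {
  dur <- max(timeline$end)
  t <- 0.4
  e <- 0
  peaks <- numeric(0)
  phi <- cfg$ar_phi
  innov <- sqrt(1 - phi^2)
  repeat {
    a <- arousal_at(timeline, t)
    rr_mean <- 60000 / (cfg$rest_hr + a * cfg$hr_arousal_delta)
    s <- cfg$hrv_rest * cfg$hrv_arousal_shrink^a
    e <- phi * e + stats::rnorm(1L, 0, s * innov)
    peaks <- c(peaks, t)
    rr <- max(320, rr_mean + e)
    t <- t + rr / 1000
    if (t >= dur - 0.2) break
  }
  peaks
}

render_ecg <- function(peaks, dur, fs, noise_sd) {
  n <- round(dur * fs)
  y <- stats::rnorm(n, 0, noise_sd)
  tt <- (seq_len(n) - 1L) / fs
  y <- y + 0.05 * sin(2 * pi * 0.25 * tt)  # baseline wander
  add_bump <- function(center, amp, sd_s) {
    lo <- max(1L, floor((center - 4 * sd_s) * fs) + 1L)
    hi <- min(n, ceiling((center + 4 * sd_s) * fs) + 1L)
    if (hi < lo) return(invisible())
    idx <- lo:hi
    y[idx] <<- y[idx] + amp * exp(-((tt[idx] - center)^2) / (2 * sd_s^2))
  }
  for (p in peaks) {
    add_bump(p, 1, 0.012)        # R wave
    add_bump(p + 0.28, 0.2, 0.05)  # T wave
  }
  y
}

scr_kernel_peak <- function(tau_r, tau_d) {
  tpk <- log(tau_d / tau_r) * tau_r * tau_d / (tau_d - tau_r)
  list(tpk = tpk, norm = exp(-tpk / tau_d) - exp(-tpk / tau_r))
}

render_eda <- function(timeline, cfg, events) {
  dur <- max(timeline$end)
  fs <- cfg$sampling_rate
  n <- round(dur * fs)
  tt <- (seq_len(n) - 1L) / fs
  a_series <- arousal_at(timeline, tt)
  # smooth the arousal steps over ~30 s: tonic level shifts are slow by
  # definition (they sit below the phasic high-pass band)
  w <- max(1L, round(30 * fs))
  a_smooth <- as.numeric(stats::filter(a_series, rep(1 / w, w), sides = 2))
  a_smooth[is.na(a_smooth)] <- 0
  y <- cfg$tonic_level + cfg$tonic_drift * tt / 60 +
    cfg$tonic_arousal_gain * a_smooth +
    stats::rnorm(n, 0, cfg$noise_sd[["eda"]])
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      t0 <- events$onset_t[i]
      amp <- events$amplitude[i]
      tau_d <- events$tau_d[i]
      kp <- scr_kernel_peak(0.75, tau_d)
      lo <- max(1L, floor(t0 * fs) + 1L)
      hi <- min(n, ceiling((t0 + 6 * tau_d) * fs))
      if (hi < lo) next
      te <- tt[lo:hi] - t0
      y[lo:hi] <- y[lo:hi] +
        amp * (exp(-te / tau_d) - exp(-te / 0.75)) / kp$norm
    }
  }
  y
}

gen_scr_events <- function(timeline, cfg) {
  rows <- list()
  for (i in seq_len(nrow(timeline))) {
    a <- timeline$arousal[i]
    rate <- cfg$scr_rate_rest +
      (cfg$scr_rate_high - cfg$scr_rate_rest) * a / 2
    len <- timeline$end[i] - timeline$start[i]
    k <- stats::rpois(1L, rate * len / 60)
    if (k > 0L) {
      # orienting responses are discrete events: enforce a 5-s refractory
      # between onsets by thinning
      on <- sort(stats::runif(k, timeline$start[i], timeline$end[i]))
      keep <- !logical(length(on))
      last <- -Inf
      for (j in seq_along(on)) {
        if (on[j] - last < 5) keep[j] <- FALSE else last <- on[j]
      }
      on <- on[keep]
      k <- length(on)
      rows[[length(rows) + 1L]] <- data.frame(
        onset_t = on,
        amplitude = stats::runif(k, cfg$scr_amp_range[1L],
                                 cfg$scr_amp_range[2L]),
        tau_d = stats::runif(k, 2, 6))
    }
  }
  if (!length(rows)) {
    return(data.frame(onset_t = numeric(0), amplitude = numeric(0),
                      tau_d = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$onset_t), , drop = FALSE]
}

render_rsp <- function(timeline, cfg) {
  dur <- max(timeline$end)
  fs <- cfg$sampling_rate
  n <- round(dur * fs)
  tt <- (seq_len(n) - 1L) / fs
  br <- cfg$br_rest + cfg$br_arousal_delta * arousal_at(timeline, tt)
  phase <- 2 * pi * cumsum(br / 60) / fs
  15 * sin(phase) + stats::rnorm(n, 0, cfg$noise_sd[["rsp"]])
}

gen_session <- function(layout, clip_arousal, cfg) {
  timeline <- arousal_timeline(layout, clip_arousal)
  dur <- max(timeline$end)
  fs <- cfg$sampling_rate
  peaks <- gen_beats(timeline, cfg)
  ecg <- biosignal_record("ecg", render_ecg(peaks, dur, fs,
                                            cfg$noise_sd[["ecg"]]), fs, 0)
  scr <- gen_scr_events(timeline, cfg)
  eda <- biosignal_record("eda", render_eda(timeline, cfg, scr), fs, 0)
  records <- list(ecg = ecg, eda = eda)
  if (cfg$include_rsp) {
    records$rsp <- biosignal_record("rsp", render_rsp(timeline, cfg), fs, 0)
  }
  br <- data.frame(start = timeline$start, end = timeline$end,
                   br = cfg$br_rest + cfg$br_arousal_delta * timeline$arousal)
  list(records = records, timeline = timeline, r_peaks = peaks,
       scr_events = scr, br = br)
}

latent_rating <- function(a) pmax(1L, 2L * as.integer(a))

gen_ratings <- function(layout, clip_arousal, cfg) {
  clips <- layout_segments(layout, "clip")
  idx <- c(4L, 8L, 12L, 16L)
  val <- latent_rating(clip_arousal[idx])
  flip <- stats::runif(4L) < cfg$rating_noise
  val <- val + ifelse(flip, sample(c(-1L, 1L), 4L, replace = TRUE), 0L)
  val <- pmin(4L, pmax(1L, val))
  data.frame(time = clips$end[match(idx, clips$clip_index)],
             after_clip_index = idx, value = val)
}

default_assignment <- function() c(rep(2L, 5L), rep(1L, 6L), rep(0L, 5L))

#' Generate a synthetic cohort
#'
#' Emits, per subject, a training session (5-minute rest) and a complete
#' exposure session with ground truth: latent arousal per segment, true
#' R-peak instants, true SCR events, the breathing-rate profile and the
#' latent ratings. The cohort is fully determined by the config seed.
#'
#' @param config A `simulation_config`.
#' @return List of elements `list(subject = subject_dataset,
#'   truth = ground_truth)`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  out <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    asg <- config$arousal_clip_assignment
    clip_arousal <- if (is.null(asg)) {
      sample(default_assignment())
    } else if (is.matrix(asg)) {
      as.integer(asg[s, ])
    } else {
      as.integer(asg)
    }
    tl <- training_layout()
    tr <- gen_session(tl, clip_arousal, config)
    ratings <- NULL
    el <- exposure_layout(data.frame(time = numeric(0),
                                     after_clip_index = integer(0),
                                     value = integer(0)))
    ratings <- gen_ratings(el, clip_arousal, config)
    el <- exposure_layout(ratings)
    ex <- gen_session(el, clip_arousal, config)
    sid <- sprintf("S%03d", s)
    subject <- subject_dataset(
      sid,
      training = list(layout = tl, records = tr$records),
      exposure = list(layout = el, records = ex$records))
    truth <- structure(list(
      subject_id = sid,
      clip_arousal = clip_arousal,
      timelines = list(training = tr$timeline, exposure = ex$timeline),
      r_peaks = list(training = tr$r_peaks, exposure = ex$r_peaks),
      scr_events = list(training = tr$scr_events, exposure = ex$scr_events),
      br = list(training = tr$br, exposure = ex$br),
      ratings = ratings), class = "ground_truth")
    out[[s]] <- list(subject = subject, truth = truth)
  }
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s: clip arousal [%s]; %d/%d exposure R-peaks/SCRs\n",
              x$subject_id, paste(x$clip_arousal, collapse = ""),
              length(x$r_peaks$exposure), nrow(x$scr_events$exposure)))
  invisible(x)
}

#' Oracle labels from the latent arousal
#'
#' Labels windows directly from the simulator's ground truth, bypassing the
#' signals, for agreement testing against the signal-driven labeling
#' approaches. Subjective configs use the noiseless rating map on the four
#' pre-rating clips; subject-based configs split the 16 clips 8/8 by latent
#' arousal (ties by clip index); clip-based configs take the latent top 3
#' and ranks 7--9.
#'
#' @param subject The `subject_dataset` the truth belongs to (for segment
#'   times).
#' @param truth A `ground_truth`.
#' @param config A `labeling_config`.
#' @return `data.frame` of labeled windows.
#' @export
truth_labels <- function(subject, truth, config) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "labeling_config"))
  a <- truth$clip_arousal
  label_by_clip <- rep(NA_character_, 16L)
  low_span <- "last_3min"
  if (config$approach == "SB") {
    idx <- c(4L, 8L, 12L, 16L)
    label_by_clip[idx] <- ifelse(latent_rating(a[idx]) >= 3, "high", "medium")
  } else if (config$approach %in% c("HR2", "EDA2")) {
    rk <- order(-a, seq_along(a))
    label_by_clip[] <- "medium"
    label_by_clip[rk[1:8]] <- "high"
    low_span <- "full_5min"
  } else {
    rk <- order(-a, seq_along(a))
    label_by_clip[rk[1:3]] <- "high"
    label_by_clip[rk[7:9]] <- "medium"
  }
  seg <- rbind(clip_segments_with_labels(subject, label_by_clip),
               rest_low_segment(subject, low_span))
  res <- finalize_windows(segment_windows(seg, config$window_s),
                          subject$subject_id, config)
  attr(res, "label_by_clip") <- label_by_clip
  res
}

#' Injected-effect contrast windows for recovery analyses
#'
#' Windows over the clips the generator injected with the full arousal
#' effect (latent level 2, labeled `high`) against the calm clips (latent
#' level 0, labeled `low`); mid-level clips are left out. This is the
#' contrast for end-to-end effect-recovery checks: both classes come from
#' the exposure session, so session-level differences cannot masquerade as
#' recovered effect, and the signal-ranked labeling approaches are not
#' involved, so ranking a signal and then classifying on the same signal's
#' features cannot inflate agreement. With the default 5/6/5 arousal
#' assignment the two classes are exactly balanced.
#'
#' @param subject The `subject_dataset` the truth belongs to.
#' @param truth A `ground_truth`.
#' @param window_s Window length in seconds.
#' @return `data.frame` of labeled windows with the clip-label map in
#'   attribute `label_by_clip`.
#' @export
arousal_contrast_labels <- function(subject, truth, window_s = 60) {
  stopifnot(inherits(truth, "ground_truth"))
  a <- truth$clip_arousal
  label_by_clip <- rep(NA_character_, 16L)
  label_by_clip[a == 2L] <- "high"
  label_by_clip[a == 0L] <- "low"
  seg <- clip_segments_with_labels(subject, label_by_clip)
  win <- segment_windows(seg, window_s)
  res <- data.frame(subject_id = subject$subject_id, session = win$session,
                    start = win$start, end = win$end, label = win$label,
                    clip_index = win$clip_index, approach = "truth",
                    levels = 2L, window_s = window_s, row.names = NULL)
  attr(res, "label_by_clip") <- label_by_clip
  res
}
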