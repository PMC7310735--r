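test_that("biosignal_record validates and reports its geometry", {
  r <- biosignal_record("ecg", rnorm(250), sampling_rate = 100, t0 = 3)
  expect_equal(record_duration(r), 2.5)
  tt <- record_times(r)
  expect_equal(tt[1L], 3)
  expect_equal(tt[2L] - tt[1L], 0.01)
  expect_equal(length(tt), 250L)
  expect_error(biosignal_record("emg", rnorm(10)), "arg")
  expect_error(biosignal_record("ecg", rnorm(10), sampling_rate = 0))
})

test_that("slice_record is half-open and composes", {
  r <- biosignal_record("eda", seq_len(1000), 100, t0 = 0)
  s <- slice_record(r, 1, 2)
  expect_equal(length(s$samples), 100L)
  expect_equal(s$t0, 1)
  expect_equal(s$samples[1L], 101)  # sample at t = 1.00
  expect_equal(s$samples[100L], 200)  # last sample before t = 2.00
  # slicing twice equals slicing once
  s2 <- slice_record(slice_record(r, 0.5, 5), 1, 2)
  expect_identical(s2$samples, s$samples)
  # empty overlap
  expect_length(slice_record(r, 20, 30)$samples, 0L)
})

test_that("session_layout enforces the invariants", {
  seg <- data.frame(role = c("rest", "clip"), clip_index = c(NA, 1L),
                    start = c(0, 300), end = c(300, 360))
  expect_s3_class(session_layout("training", seg), "session_layout")
  bad <- seg
  bad$start[2L] <- 200  # overlaps the rest
  expect_error(session_layout("training", bad), "overlap")
  bad2 <- seg
  bad2$end[1L] <- 0
  expect_error(session_layout("training", bad2), "exceed")
  bad3 <- seg
  bad3$clip_index[2L] <- NA
  expect_error(session_layout("training", bad3), "clip_index")
  expect_error(
    session_layout("training", seg,
                   ratings = data.frame(time = 1, after_clip_index = 1L,
                                        value = 7L)),
    "1..4")
})

test_that("session CSV round trip is bit-exact with lossless metadata", {
  set.seed(42)
  fs <- 100
  dur <- 20
  recs <- list(ecg = biosignal_record("ecg", rnorm(dur * fs), fs),
               eda = biosignal_record("eda", 2 + cumsum(rnorm(dur * fs, 0, 1e-3)), fs),
               rsp = biosignal_record("rsp", 15 * sin(seq_len(dur * fs) / 40), fs))
  seg <- data.frame(role = c("demo", "clip"), clip_index = c(NA, 3L),
                    start = c(0, 10), end = c(10, 20))
  lay <- session_layout("exposure", seg,
                        ratings = data.frame(time = 20, after_clip_index = 3L,
                                             value = 4L))
  path <- file.path(tempdir(), "sess.csv")
  write_session(lay, recs, path)
  # one row per sample tick plus the header
  expect_equal(length(readLines(path)), dur * fs + 1L)
  got <- read_session(path)
  for (ch in names(recs)) {
    expect_identical(got$records[[ch]]$samples, recs[[ch]]$samples)
    expect_equal(got$records[[ch]]$sampling_rate, fs)
  }
  expect_equal(got$layout$session_kind, "exposure")
  expect_equal(got$layout$segments$start, seg$start)
  expect_equal(got$layout$segments$end, seg$end)
  expect_equal(got$layout$segments$clip_index, seg$clip_index)
  expect_equal(got$layout$ratings$value, 4L)
  unlink(c(path, sub("csv$", "json", path)))
})

test_that("write_session rejects an empty channel map; read flags bad input", {
  lay <- session_layout("training",
                        data.frame(role = "rest", clip_index = NA,
                                   start = 0, end = 300))
  expect_error(write_session(lay, list(), file.path(tempdir(), "x.csv")),
               "empty channel map")
  expect_error(read_session(file.path(tempdir(), "nope.csv")), "no signal")
  # signal file present but sidecar missing
  p <- file.path(tempdir(), "orphan.csv")
  writeLines("t,ecg\n0,1", p)
  expect_error(read_session(p), "sidecar")
  unlink(p)
})

test_that("read_session rejects a corrupted sidecar with overlapping segments", {
  fs <- 100
  recs <- list(ecg = biosignal_record("ecg", rnorm(500), fs),
               eda = biosignal_record("eda", rep(2, 500), fs))
  lay <- session_layout("training",
                        data.frame(role = "rest", clip_index = NA,
                                   start = 0, end = 5))
  path <- file.path(tempdir(), "corrupt.csv")
  write_session(lay, recs, path)
  sp <- sub("csv$", "json", path)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  meta$segments <- data.frame(role = c("rest", "rest"),
                              clip_index = c(NA, NA),
                              start = c(0, 2), end = c(5, 6))
  jsonlite::write_json(meta, sp, auto_unbox = TRUE, dataframe = "columns")
  expect_error(read_session(path), "overlap")
  unlink(c(path, sp))
})

test_that("OpenSignals dialect is read and resampled to the sidecar rate", {
  p <- file.path(tempdir(), "osig.txt")
  hdr <- '# {"sampling rate": 50, "column": ["nSeq", "ECG", "EDA"]}'
  set.seed(7)
  n <- 500
  body <- sprintf("%d %.6f %.6f", seq_len(n), rnorm(n), 2 + rnorm(n, 0, 0.01))
  writeLines(c("# OpenSignals text dialect", hdr, "# EndOfHeader", body), p)
  rec <- read_opensignals(p)
  expect_setequal(names(rec), c("ecg", "eda"))
  expect_equal(rec$ecg$sampling_rate, 50)
  expect_equal(length(rec$ecg$samples), n)
  # full read path with a sidecar declaring 100 Hz: channels are resampled
  lay <- session_layout("training",
                        data.frame(role = "rest", clip_index = NA,
                                   start = 0, end = 10))
  meta <- list(session_kind = "training", segments = lay$segments,
               ratings = lay$ratings, sampling_rate = 100,
               t0 = 0, channels = c("ecg", "eda"))
  jsonlite::write_json(meta, sub("txt$", "json", p), auto_unbox = TRUE,
                       dataframe = "columns")
  got <- read_session(p)
  expect_equal(got$records$ecg$sampling_rate, 100)
  expect_equal(record_duration(got$records$ecg), 10, tolerance = 0.01)
  unlink(c(p, sub("txt$", "json", p)))
})

test_that("compute_baseline recovers known resting values", {
  fs <- 100
  dur <- 300
  peaks <- const_hr_peaks(60, dur)
  ecg <- make_ecg_record(peaks, dur, fs)
  set.seed(3)
  eda <- biosignal_record("eda", 3 + 0.3 * sin(2 * pi * 0.01 *
                                                 (seq_len(dur * fs) - 1) / fs),
                          fs)
  rsp <- make_rsp_record(15, dur, fs)
  lay <- session_layout("training",
                        data.frame(role = "rest", clip_index = NA,
                                   start = 0, end = dur))
  elay <- session_layout("exposure",
                         data.frame(role = "demo", clip_index = NA,
                                    start = 0, end = 60))
  erecs <- list(ecg = make_ecg_record(const_hr_peaks(80, 60), 60, fs, seed = 9),
                eda = biosignal_record("eda", rep(3, 60 * fs), fs))
  subj <- subject_dataset("T01",
                          training = list(layout = lay,
                                          records = list(ecg = ecg, eda = eda,
                                                         rsp = rsp)),
                          exposure = list(layout = elay, records = erecs))
  b <- compute_baseline(subj, "full_5min")
  expect_equal(b$hr_rest_mean, 60, tolerance = 1)
  expect_equal(b$br_rest_mean, 15, tolerance = 1)
  expect_equal(b$eda_rest_min, 2.7, tolerance = 0.05)
  expect_equal(b$eda_rest_max, 3.3, tolerance = 0.05)
  # the baseline never looks at the exposure session
  subj2 <- subj
  subj2$exposure$records$ecg <- make_ecg_record(const_hr_peaks(110, 60), 60,
                                                fs, seed = 10)
  b2 <- compute_baseline(subj2, "full_5min")
  expect_identical(b2$hr_rest_mean, b$hr_rest_mean)
  # last_3min on a stationary rest agrees within noise
  b3 <- compute_baseline(subj, "last_3min")
  expect_equal(b3$hr_rest_mean, b$hr_rest_mean, tolerance = 1)
  expect_equal(b3$rest_window, c(120, 300))
})

test_that("compute_baseline rejects a too-short rest", {
  fs <- 100
  dur <- 120
  lay <- session_layout("training",
                        data.frame(role = "rest", clip_index = NA,
                                   start = 0, end = dur))
  elay <- session_layout("exposure",
                         data.frame(role = "demo", clip_index = NA,
                                    start = 0, end = 60))
  recs <- list(ecg = make_ecg_record(const_hr_peaks(60, dur), dur, fs),
               eda = biosignal_record("eda", rep(2, dur * fs), fs))
  erecs <- list(ecg = make_ecg_record(const_hr_peaks(60, 60), 60, fs),
                eda = biosignal_record("eda", rep(2, 60 * fs), fs))
  subj <- subject_dataset("T02",
                          training = list(layout = lay, records = recs),
                          exposure = list(layout = elay, records = erecs))
  expect_error(compute_baseline(subj, "full_5min"), "120 s")
  expect_error(compute_baseline(subj, "last_3min"), "180 s")
})

test_that("subject_dataset requires ECG and EDA in both sessions", {
  lay <- session_layout("training",
                        data.frame(role = "rest", clip_index = NA,
                                   start = 0, end = 300))
  elay <- session_layout("exposure",
                         data.frame(role = "demo", clip_index = NA,
                                    start = 0, end = 60))
  ecg <- biosignal_record("ecg", rnorm(100))
  eda <- biosignal_record("eda", rnorm(100))
  expect_error(
    subject_dataset("X", training = list(layout = lay, records = list(ecg = ecg)),
                    exposure = list(layout = elay,
                                    records = list(ecg = ecg, eda = eda))),
    "missing required channel")
  expect_error(
    subject_dataset("X",
                    training = list(layout = elay,
                                    records = list(ecg = ecg, eda = eda)),
                    exposure = list(layout = elay,
                                    records = list(ecg = ecg, eda = eda))),
    "kinds")
})
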