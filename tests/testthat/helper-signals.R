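# Small synthetic-record builders used across the unit tests. These are
# deliberately independent of the package's simulator internals.

# ECG as Gaussian R-wave bumps at given instants on low noise
make_ecg_record <- function(peak_times, duration, fs = 100, noise_sd = 0.02,
                            seed = 1, t0 = 0) {
  set.seed(seed)
  n <- round(duration * fs)
  tt <- t0 + (seq_len(n) - 1L) / fs
  y <- rnorm(n, 0, noise_sd)
  for (p in peak_times) {
    y <- y + exp(-((tt - p)^2) / (2 * 0.012^2))
  }
  biosignal_record("ecg", y, fs, t0)
}

# evenly spaced beats at a constant heart rate
const_hr_peaks <- function(hr, duration, start = 0.5) {
  seq(start, duration - 0.3, by = 60 / hr)
}

# EDA: constant tonic level plus biexponential SCRs of known amplitude
make_scr_eda <- function(onsets, amps, duration, fs = 100, level = 2,
                         tau_r = 0.75, tau_d = 4, noise_sd = 0, seed = 1,
                         drift_per_s = 0) {
  set.seed(seed)
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1L) / fs
  y <- level + drift_per_s * tt + rnorm(n, 0, noise_sd)
  tpk <- log(tau_d / tau_r) * tau_r * tau_d / (tau_d - tau_r)
  norm <- exp(-tpk / tau_d) - exp(-tpk / tau_r)
  for (i in seq_along(onsets)) {
    te <- tt - onsets[i]
    k <- ifelse(te >= 0, (exp(-te / tau_d) - exp(-te / tau_r)) / norm, 0)
    y <- y + amps[i] * k
  }
  biosignal_record("eda", y, fs, 0)
}

# RSP: sinusoid at a given breathing rate
make_rsp_record <- function(br, duration, fs = 100, amp = 15, noise_sd = 0.3,
                            seed = 1) {
  set.seed(seed)
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1L) / fs
  y <- amp * sin(2 * pi * (br / 60) * tt) + rnorm(n, 0, noise_sd)
  biosignal_record("rsp", y, fs, 0)
}

# a baseline object with known values, bypassing signal processing
make_baseline <- function(hr = 70, br = 14, eda_min = 2, eda_max = 4,
                          id = "T001") {
  structure(list(subject_id = id, hr_rest_mean = hr, br_rest_mean = br,
                 eda_rest_min = eda_min, eda_rest_max = eda_max,
                 rest_window = c(0, 300)),
            class = "anx_baseline")
}

# an nni_series whose in-window intervals are exactly iv_ms
make_nni <- function(iv_ms, start = 0.5) {
  nni_series(cumsum(c(start, iv_ms / 1000)))
}

# well-separated Gaussian blobs for classifier tests
make_blobs <- function(n_per_class, p = 2, sep = 4,
                       classes = c("low", "high"), seed = 1) {
  set.seed(seed)
  xs <- list()
  ys <- character(0)
  for (j in seq_along(classes)) {
    m <- matrix(rnorm(n_per_class * p), n_per_class, p)
    m[, 1L] <- m[, 1L] + (j - 1L) * sep
    xs[[j]] <- m
    ys <- c(ys, rep(classes[j], n_per_class))
  }
  x <- as.data.frame(do.call(rbind, xs))
  names(x) <- paste0("f", seq_len(p))
  list(x = x, y = factor(ys, levels = classes))
}
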