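# Naive, loop-based re-implementations of the feature formulas. These are the
# independent oracles the vectorized implementations are checked against; they
# transcribe each definition literally and share no code with the package.

o_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

o_sd <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- o_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / (n - 1L))
}

# normalized mean: mean of the series minus the resting mean
o_nmean <- function(x, rest_mean) o_mean(x) - rest_mean

# normalized first difference of the within-window z-scored series
o_nfd <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  s <- o_sd(x)
  if (!isTRUE(s > 0)) return(0)
  m <- o_mean(x)
  z <- (x - m) / s
  acc <- 0
  for (i in 1:(n - 1L)) acc <- acc + abs(z[i + 1L] - z[i])
  acc / (n - 1L)
}

# normalized second difference (lag 2) of the z-scored series
o_nsd <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  s <- o_sd(x)
  if (!isTRUE(s > 0)) return(0)
  m <- o_mean(x)
  z <- (x - m) / s
  acc <- 0
  for (i in 1:(n - 2L)) acc <- acc + abs(z[i + 2L] - z[i])
  acc / (n - 2L)
}

# signed-difference variability: (1/N) * sum of successive differences
o_hrv <- function(iv) {
  n <- length(iv)
  if (n < 2L) return(NA_real_)
  acc <- 0
  for (i in 1:(n - 1L)) acc <- acc + (iv[i + 1L] - iv[i])
  acc / n
}

o_rmssd <- function(iv) {
  n <- length(iv)
  if (n < 2L) return(NA_real_)
  acc <- 0
  for (i in 1:(n - 1L)) acc <- acc + (iv[i + 1L] - iv[i])^2
  sqrt(acc / (n - 1L))
}

o_nn50 <- function(iv) {
  n <- length(iv)
  if (n < 2L) return(NA_real_)
  k <- 0
  for (i in 1:(n - 1L)) if (abs(iv[i + 1L] - iv[i]) > 50) k <- k + 1
  k
}

o_pnn <- function(iv, thr) {
  n <- length(iv)
  if (n < 2L) return(NA_real_)
  k <- 0
  for (i in 1:(n - 1L)) if (abs(iv[i + 1L] - iv[i]) > thr) k <- k + 1
  k / (n - 1L)
}

# kappa straight from the definition, accumulating cell by cell
o_kappa <- function(cm) {
  n <- sum(cm)
  po <- 0
  for (i in seq_len(nrow(cm))) po <- po + cm[i, i]
  po <- po / n
  pe <- 0
  for (i in seq_len(nrow(cm))) pe <- pe + sum(cm[i, ]) * sum(cm[, i])
  pe <- pe / n^2
  (po - pe) / (1 - pe)
}

# compare two named numeric vectors at relative tolerance
expect_rel_equal <- function(got, want, rel = 1e-9) {
  for (nm in names(want)) {
    g <- got[[nm]]
    w <- want[[nm]]
    if (is.na(w)) {
      expect_true(is.na(g), label = paste0(nm, " expected NA"))
    } else {
      denom <- max(abs(w), 1e-12)
      expect_lt(abs(g - w) / denom, rel,
                label = sprintf("%s: |%.12g - %.12g|/%g", nm, g, w, denom))
    }
  }
  invisible(TRUE)
}
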