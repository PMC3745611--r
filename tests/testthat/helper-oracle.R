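# Independent reference implementations used as oracles. These are literal,
# unoptimized transcriptions kept deliberately separate from the package
# code paths they check.

# Reference saccade/fixation detector: extract supra-threshold runs, gate
# by duration, merge across short gaps until nothing changes, complement.
# Takes a precomputed speed series; returns list(saccades, fixations) as
# data.frames with onset/offset.
oracle_detect <- function(t, speed, velocity_threshold, min_saccade_ms,
                          min_fixation_ms) {
  supra <- !is.na(speed) & speed > velocity_threshold
  n <- length(t)
  # maximal runs, by explicit scan
  cand <- data.frame(onset = numeric(0), offset = numeric(0))
  i <- 1
  while (i <= n) {
    if (supra[i]) {
      j <- i
      while (j < n && supra[j + 1]) j <- j + 1
      if (t[j] - t[i] >= min_saccade_ms) {
        cand <- rbind(cand, data.frame(onset = t[i], offset = t[j]))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  # iterative merging until fixpoint
  repeat {
    if (nrow(cand) < 2) break
    merged <- FALSE
    for (k in seq_len(nrow(cand) - 1)) {
      if (cand$onset[k + 1] - cand$offset[k] < min_fixation_ms) {
        cand$offset[k] <- cand$offset[k + 1]
        cand <- cand[-(k + 1), ]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  fix <- data.frame(onset = numeric(0), offset = numeric(0))
  bounds <- c(t[1], rbind(cand$onset, cand$offset), t[n])
  for (k in seq(1, length(bounds) - 1, by = 2)) {
    if (bounds[k + 1] > bounds[k]) {
      fix <- rbind(fix, data.frame(onset = bounds[k], offset = bounds[k + 1]))
    }
  }
  list(saccades = cand, fixations = fix)
}

# Exact magnitude response of the digital (bilinear-transform) Butterworth
# low-pass of given order: |H(f)|^2 with prewarped frequencies. A
# zero-phase forward-backward pass has magnitude |H|^2, so its attenuation
# of a pure sine is this value.
butter_zero_phase_gain <- function(f_hz, cutoff_hz, rate_hz, order = 3) {
  ratio <- tan(pi * f_hz / rate_hz) / tan(pi * cutoff_hz / rate_hz)
  1 / (1 + ratio^(2 * order))
}

# Amplitude of a sinusoid of known frequency by quadrature projection
# (robust to the sample grid missing the waveform peaks). Use a window
# holding an integer number of cycles.
sine_amplitude <- function(x, f_hz, rate_hz) {
  tt <- (seq_along(x) - 1) / rate_hz
  2 * sqrt(mean(x * sin(2 * pi * f_hz * tt))^2 +
             mean(x * cos(2 * pi * f_hz * tt))^2)
}

# Mean and sd of a normal distribution truncated to [lo, hi]: the correct
# expected value/scale of latencies drawn from a truncated-normal model and
# further selected by a validity window.
tnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  Z <- pnorm(b) - pnorm(a)
  mu + sd * (dnorm(a) - dnorm(b)) / Z
}

tnorm_sd <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  Z <- pnorm(b) - pnorm(a)
  sd * sqrt(1 + (a * dnorm(a) - b * dnorm(b)) / Z -
              ((dnorm(a) - dnorm(b)) / Z)^2)
}

# Lag (in samples) of the peak of the cross-correlation between two equal
# length series, searched over a symmetric lag window.
xcorr_peak_lag <- function(x, y, max_lag = 20) {
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      sum(x[seq_len(length(x) - l)] * y[seq_len(length(y) - l) + l])
    } else {
      sum(x[seq_len(length(x) + l) - l] * y[seq_len(length(y) + l)])
    }
  }, numeric(1))
  lags[which.max(cc)]
}
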