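#' Specify a zero-phase low-pass filter
#'
#' Describes the filter applied to gaze traces before velocity computation:
#' a Butterworth low-pass run forward and then backward over each
#' contiguous valid segment, so the net group delay is zero and the
#' effective magnitude response is the single-pass response squared.
#' Defaults (third order, 60 Hz cutoff) suit gaze data sampled above
#' 120 Hz; at 120 Hz the cutoff equals the Nyquist frequency and filtering
#' must be skipped.
#'
#' @param cutoff_hz Cutoff frequency, Hz. Must be strictly below half the
#'   sampling rate at application time.
#' @param order Filter order (default 3).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz = 60, order = 3L) {
  stopifnot(is.numeric(cutoff_hz), cutoff_hz > 0,
            is.numeric(order), order >= 1)
  structure(list(cutoff_hz = cutoff_hz, order = as.integer(order)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf(
    "<filter_spec> zero-phase Butterworth low-pass, order %d, cutoff %g Hz\n",
    x$order, x$cutoff_hz))
  invisible(x)
}

# steady-state initial filter state for a unit-amplitude step input
# (direct form II transposed), so transients at segment edges vanish
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b)))
  a <- c(a, rep(0, nf - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  comp <- rbind(-a[-1], cbind(diag(nf - 2), rep(0, nf - 2)))
  solve(diag(nf - 1) - t(comp), b[-1] - a[-1] * b[1])
}

# forward-backward pass on one contiguous numeric vector with
# odd-reflection padding of length min(3 * (order + 1), n - 1)
filtfilt_segment <- function(x, b, a, order) {
  n <- length(x)
  pad <- min(3L * (order + 1L), n - 1L)
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  ext <- c(left, x, right)
  zi <- lfilter_zi(b, a)
  y <- lfilter_df2t(b, a, ext, zi * ext[1])
  y <- rev(lfilter_df2t(b, a, rev(y), zi * y[length(y)]))
  y[seq(pad + 1, pad + n)]
}

# maximal runs of valid samples; returns list of index vectors
valid_segments <- function(valid) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  purrr::map2(starts[r$values], ends[r$values], seq.int)
}

#' Zero-phase low-pass filtering of a gaze trace
#'
#' Applies the forward-backward Butterworth filter described by a
#' [filter_spec()] to the `x` and `y` columns of a sample stream,
#' independently per axis. Tracking-loss gaps split the trace: each
#' contiguous valid segment of at least `3 * (order + 1)` samples is
#' filtered independently with odd-reflection edge padding; shorter
#' segments pass through unfiltered and are flagged. Invalid samples and
#' all timestamps are left untouched; gaps are never interpolated.
#'
#' @param samples Data frame with columns `t`, `x`, `y`, `valid` (a single
#'   trial). A `trial` column, if present, is preserved.
#' @param spec A [filter_spec()].
#' @param rate_hz Sampling rate used for the filter design. `NULL` infers
#'   the rate from the median intersample interval.
#' @return The input tibble with `x`, `y` replaced by filtered values and a
#'   logical column `filtered` marking samples that were actually filtered.
#' @examples
#' tr <- data.frame(t = seq(0, 998, by = 2), x = 1, y = -2, valid = TRUE)
#' out <- lowpass_zero_phase(tr, filter_spec(60), rate_hz = 500)
#' all.equal(out$x, tr$x)  # DC gain is exactly 1
#' @export
lowpass_zero_phase <- function(samples, spec = filter_spec(),
                               rate_hz = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  samples <- tibble::as_tibble(as.data.frame(samples))
  stopifnot(all(c("t", "x", "y", "valid") %in% names(samples)))
  if (is.null(rate_hz)) {
    rate_hz <- 1000 / stats::median(diff(samples$t))
  }
  if (spec$cutoff_hz >= rate_hz / 2) {
    abort(sprintf(
      "cutoff (%g Hz) must be below the Nyquist frequency (%g Hz); skip filtering instead",
      spec$cutoff_hz, rate_hz / 2))
  }
  bt <- signal::butter(spec$order, 2 * spec$cutoff_hz / rate_hz, type = "low")
  min_len <- 3L * (spec$order + 1L)
  out <- samples
  out$filtered <- FALSE
  for (idx in valid_segments(samples$valid)) {
    if (length(idx) >= min_len) {
      out$x[idx] <- filtfilt_segment(samples$x[idx], bt$b, bt$a, spec$order)
      out$y[idx] <- filtfilt_segment(samples$y[idx], bt$b, bt$a, spec$order)
      out$filtered[idx] <- TRUE
    }
  }
  out
}

#' Gaze speed from a sample stream
#'
#' Estimates instantaneous speed (degrees/s) by central differences on the
#' actual timestamps: `speed[i] = |p[i+1] - p[i-1]| / (t[i+1] - t[i-1]) *
#' 1000`, with one-sided differences at segment endpoints. Speeds are
#' computed within each contiguous run of valid samples; runs shorter than
#' 3 samples, and all invalid samples, get `NA` (speed is undefined across
#' tracking loss). Actual timestamps are used rather than the nominal rate
#' because recorded intervals jitter.
#'
#' @param samples Data frame with columns `t`, `x`, `y`, `valid`.
#' @return Numeric vector of speeds, one per sample (NA where undefined).
#' @export
gaze_velocity <- function(samples) {
  samples <- as.data.frame(samples)
  stopifnot(all(c("t", "x", "y", "valid") %in% names(samples)))
  n <- nrow(samples)
  speed <- rep(NA_real_, n)
  for (idx in valid_segments(samples$valid)) {
    m <- length(idx)
    if (m < 3) next
    t <- samples$t[idx]; x <- samples$x[idx]; y <- samples$y[idx]
    i <- 2:(m - 1)
    s <- numeric(m)
    s[i] <- sqrt((x[i + 1] - x[i - 1])^2 + (y[i + 1] - y[i - 1])^2) /
      (t[i + 1] - t[i - 1]) * 1000
    s[1] <- sqrt((x[2] - x[1])^2 + (y[2] - y[1])^2) / (t[2] - t[1]) * 1000
    s[m] <- sqrt((x[m] - x[m - 1])^2 + (y[m] - y[m - 1])^2) /
      (t[m] - t[m - 1]) * 1000
    speed[idx] <- s
  }
  speed
}
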