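#' Saccade-detection parameters
#'
#' The three parameters of the velocity-threshold detector: samples whose
#' speed exceeds `velocity_threshold` form candidate runs; runs spanning at
#' least `min_saccade_ms` are saccade candidates; successive candidates
#' separated by less than `min_fixation_ms` are merged. Defaults are the
#' values used for 120-Hz video-based recordings (22 deg/s, 12 ms, 12 ms).
#'
#' @param velocity_threshold Speed threshold, degrees/s.
#' @param min_saccade_ms Minimum saccade duration, ms.
#' @param min_fixation_ms Minimum fixation duration (merge criterion), ms.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(velocity_threshold = 22, min_saccade_ms = 12,
                             min_fixation_ms = 12) {
  stopifnot(velocity_threshold > 0, min_saccade_ms > 0, min_fixation_ms > 0)
  structure(list(velocity_threshold = velocity_threshold,
                 min_saccade_ms = min_saccade_ms,
                 min_fixation_ms = min_fixation_ms),
            class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf(
    "<detection_params> threshold %g deg/s, min saccade %g ms, min fixation %g ms\n",
    x$velocity_threshold, x$min_saccade_ms, x$min_fixation_ms))
  invisible(x)
}

#' Merge saccade candidates separated by short gaps
#'
#' Single left-to-right pass over sorted, disjoint candidate intervals:
#' whenever the gap between the current merged interval's offset and the
#' next interval's onset is strictly shorter than `min_fixation_ms`, the
#' two are merged (spanning first onset to last offset). The pass is
#' idempotent: every surviving gap is at least `min_fixation_ms`.
#'
#' @param candidates Data frame with numeric columns `onset` and `offset`
#'   (ms), sorted by onset and non-overlapping.
#' @param min_fixation_ms Merge threshold, ms.
#' @return A tibble with columns `onset`, `offset`.
#' @examples
#' cand <- data.frame(onset = c(0, 24, 60, 81), offset = c(16, 40, 76, 97))
#' merge_candidates(cand, 12)  # gaps 8, 20, 5 -> 1st and 3rd merged
#' @export
merge_candidates <- function(candidates, min_fixation_ms) {
  candidates <- as.data.frame(candidates)
  stopifnot(all(c("onset", "offset") %in% names(candidates)))
  n <- nrow(candidates)
  if (n == 0) return(tibble::tibble(onset = numeric(), offset = numeric()))
  if (is.unsorted(candidates$onset, strictly = FALSE) ||
      any(candidates$onset[-1] < candidates$offset[-n])) {
    abort("candidates must be sorted by onset and non-overlapping")
  }
  onset <- candidates$onset[1]
  offset <- candidates$offset[1]
  if (n > 1) {
    for (i in 2:n) {
      if (candidates$onset[i] - offset[length(offset)] < min_fixation_ms) {
        offset[length(offset)] <- candidates$offset[i]
      } else {
        onset <- c(onset, candidates$onset[i])
        offset <- c(offset, candidates$offset[i])
      }
    }
  }
  tibble::new_tibble(list(onset = onset, offset = offset),
                     nrow = length(onset))
}

#' Detect saccades and fixations in a gaze trace
#'
#' Velocity-threshold event detection with duration gating and candidate
#' merging, staged exactly as: (1) compute sample speeds (optionally on the
#' zero-phase low-pass filtered trace); (2) take maximal runs of samples
#' with speed strictly above the velocity threshold; (3) keep runs whose
#' time span (last minus first supra-threshold sample) is at least
#' `min_saccade_ms`; (4) merge successive candidates whose gap is shorter
#' than `min_fixation_ms`; (5) surviving candidates are saccades and the
#' complementary intervals are fixations. A run's onset is the time of its
#' first supra-threshold sample. A merged saccade's start/end positions
#' (hence amplitude) are taken at the merged onset and offset. Events whose
#' span touches invalid (tracking-loss) samples are kept but flagged
#' `unreliable`.
#'
#' By default the trace is filtered (60 Hz zero-phase Butterworth) when the
#' sampling rate exceeds 120 Hz and left raw otherwise, mirroring the fact
#' that 120-Hz data contain no energy above their 60-Hz Nyquist frequency.
#'
#' @param samples One trial's samples: data frame with columns `t`, `x`,
#'   `y`, `valid` (at least 3 valid samples).
#' @param params A [detection_params()].
#' @param filter A [filter_spec()], `NULL` for no filtering, or `"auto"`
#'   (default) for the rate-dependent rule above.
#' @param rate_hz Sampling rate; `NULL` infers it from median intervals.
#' @param speed Optional precomputed speed series (deg/s, one value per
#'   sample, NA where undefined), e.g. from a custom velocity estimator.
#'   When supplied, `filter` is ignored for speed computation and event
#'   positions are read from the raw samples.
#' @return A `gaze_events` tibble with columns `event` ("saccade" or
#'   "fixation"), `onset`, `offset`, `duration` (ms), `x0`, `y0`, `x1`,
#'   `y1`, `amplitude` (deg), `peak_velocity` (deg/s), `cx`, `cy` (fixation
#'   centroid) and `unreliable`, ordered by onset.
#' @export
detect_events <- function(samples, params = detection_params(),
                          filter = "auto", rate_hz = NULL, speed = NULL) {
  stopifnot(inherits(params, "detection_params"))
  samples <- tibble::as_tibble(as.data.frame(samples))
  stopifnot(all(c("t", "x", "y", "valid") %in% names(samples)))
  if (sum(samples$valid) < 3) {
    abort("detection requires at least 3 valid samples")
  }
  if (is.null(speed)) {
    if (is.null(rate_hz)) rate_hz <- 1000 / stats::median(diff(samples$t))
    if (identical(filter, "auto")) {
      filter <- if (rate_hz > 120) filter_spec() else NULL
    }
    work <- if (is.null(filter)) samples else
      lowpass_zero_phase(samples, filter, rate_hz)
    speed <- gaze_velocity(work)
  } else {
    stopifnot(length(speed) == nrow(samples))
    work <- samples
  }
  supra <- !is.na(speed) & speed > params$velocity_threshold

  t <- work$t
  n <- length(t)
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ci <- r$values
  cand_first <- starts[ci]
  cand_last <- ends[ci]
  keep <- (t[cand_last] - t[cand_first]) >= params$min_saccade_ms
  sac <- merge_candidates(
    tibble::new_tibble(list(onset = t[cand_first[keep]],
                            offset = t[cand_last[keep]]),
                       nrow = sum(keep)),
    params$min_fixation_ms)

  # cumulative invalid counts for O(1) "touches invalid" queries
  # (invalid inside the span or immediately adjacent to it)
  cum_inv <- cumsum(!work$valid)
  touches_invalid <- function(i0, i1) {
    lo <- pmax(i0 - 1L, 1L)
    hi <- pmin(i1 + 1L, n)
    (cum_inv[hi] - cum_inv[lo] + !work$valid[lo]) > 0
  }

  ns <- nrow(sac)
  i_on <- match(sac$onset, t)
  i_off <- match(sac$offset, t)
  nf_on <- c(t[1], sac$offset)
  nf_off <- c(sac$onset, t[n])
  fkeep <- nf_off > nf_on
  fix_on <- nf_on[fkeep]
  fix_off <- nf_off[fkeep]
  f_i0 <- c(1L, i_off)[fkeep]
  f_i1 <- c(i_on, n)[fkeep]
  nf <- length(fix_on)

  cen_x <- cen_y <- numeric(nf)
  for (i in seq_len(nf)) {
    sel <- seq.int(f_i0[i], f_i1[i])
    sel <- sel[work$valid[sel]]
    cen_x[i] <- mean(work$x[sel])
    cen_y[i] <- mean(work$y[sel])
  }
  pv <- numeric(ns)
  for (i in seq_len(ns)) {
    pv[i] <- max(speed[seq.int(i_on[i], i_off[i])], na.rm = TRUE)
  }

  onset <- c(sac$onset, fix_on)
  out <- tibble::new_tibble(list(
    event = rep(c("saccade", "fixation"), c(ns, nf)),
    onset = onset,
    offset = c(sac$offset, fix_off),
    duration = c(sac$offset - sac$onset, fix_off - fix_on),
    x0 = c(work$x[i_on], rep(NA_real_, nf)),
    y0 = c(work$y[i_on], rep(NA_real_, nf)),
    x1 = c(work$x[i_off], rep(NA_real_, nf)),
    y1 = c(work$y[i_off], rep(NA_real_, nf)),
    amplitude = c(sqrt((work$x[i_off] - work$x[i_on])^2 +
                         (work$y[i_off] - work$y[i_on])^2),
                  rep(NA_real_, nf)),
    peak_velocity = c(pv, rep(NA_real_, nf)),
    cx = c(rep(NA_real_, ns), cen_x),
    cy = c(rep(NA_real_, ns), cen_y),
    unreliable = c(touches_invalid(i_on, i_off) & rep(TRUE, ns),
                   touches_invalid(f_i0, f_i1) & rep(TRUE, nf))
  ), nrow = ns + nf)
  out <- out[order(out$onset), ]
  class(out) <- c("gaze_events", class(out))
  out
}

#' Detect events for every trial of a recording
#'
#' Maps [detect_events()] over the trials of a [gaze_recording()]. Trials
#' with fewer than 3 valid samples yield no events and are reported in a
#' warning rather than an error.
#'
#' @param rec A `gaze_recording`.
#' @inheritParams detect_events
#' @return A `gaze_events` tibble with a leading `trial` column.
#' @export
detect_session <- function(rec, params = detection_params(),
                           filter = "auto") {
  stopifnot(inherits(rec, "gaze_recording"))
  skipped <- integer(0)
  res <- purrr::map(trial_indices(rec), function(i) {
    s <- rec$samples[rec$samples$trial == i, ]
    if (sum(s$valid) < 3) {
      skipped <<- c(skipped, i)
      return(NULL)
    }
    ev <- detect_events(s, params, filter, rate_hz = rec$nominal_rate)
    dplyr::bind_cols(tibble::tibble(trial = i), ev)
  })
  if (length(skipped)) {
    warn(sprintf("trial(s) %s skipped: fewer than 3 valid samples",
                 paste(skipped, collapse = ", ")))
  }
  out <- dplyr::bind_rows(res)
  class(out) <- c("gaze_events", class(out))
  out
}
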