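#' Build a gaze recording
#'
#' A gaze recording bundles the sample stream of one session (one or more
#' trials), the text messages interleaved with it (stimulus onsets,
#' keypresses, ...), the nominal sampling rate and the screen geometry.
#' Positions are in degrees of visual angle, screen-center origin. Samples
#' with `valid = FALSE` mark tracking loss (e.g. blinks or failed
#' Purkinje-image detection); their `x`/`y` are undefined and ignored by all
#' downstream computation — gaps are never silently interpolated.
#'
#' @param samples Data frame with columns `trial` (integer, 1-based), `t`
#'   (ms from trial start), `x`, `y` (degrees) and `valid` (logical).
#' @param messages Data frame with columns `trial`, `t` (ms) and `text`, or
#'   `NULL` for none. Message text must not contain newlines.
#' @param nominal_rate Nominal sampling rate in Hz (> 0).
#' @param geometry A [screen_geometry()] or `NULL`.
#'
#' @return An object of class `gaze_recording`: a list with tibbles
#'   `$samples` and `$messages` plus `$nominal_rate` and `$geometry`.
#' @examples
#' rec <- gaze_recording(
#'   data.frame(trial = 1L, t = c(0, 4, 8), x = 0, y = 0, valid = TRUE),
#'   data.frame(trial = 1L, t = 2, text = "TARGET_ON 4.2 0"),
#'   nominal_rate = 250
#' )
#' rec
#' @export
gaze_recording <- function(samples, messages = NULL, nominal_rate,
                           geometry = NULL) {
  samples <- tibble::as_tibble(as.data.frame(samples))
  req <- c("trial", "t", "x", "y", "valid")
  if (!all(req %in% names(samples))) {
    abort(paste("samples must have columns:", paste(req, collapse = ", ")))
  }
  samples <- samples[req]
  samples$trial <- as.integer(samples$trial)
  samples$valid <- as.logical(samples$valid)
  # canonical representation of tracking loss: positions stored as NaN
  samples$x[!samples$valid] <- NaN
  samples$y[!samples$valid] <- NaN
  if (is.null(messages)) {
    messages <- tibble::tibble(trial = integer(), t = numeric(),
                               text = character())
  } else {
    messages <- tibble::as_tibble(as.data.frame(messages))
    stopifnot(all(c("trial", "t", "text") %in% names(messages)))
    messages <- messages[c("trial", "t", "text")]
    messages$trial <- as.integer(messages$trial)
    messages$text <- as.character(messages$text)
  }
  rec <- structure(
    list(samples = samples, messages = messages,
         nominal_rate = as.numeric(nominal_rate), geometry = geometry),
    class = "gaze_recording"
  )
  validate_gaze_recording(rec)
}

#' Validate a gaze recording
#'
#' Checks the structural invariants: positive nominal rate, finite
#' non-negative timestamps, strictly increasing sample times within each
#' trial, and nondecreasing message times within each trial.
#'
#' @param rec A `gaze_recording`.
#' @return `rec`, invisibly usable, or an error describing the violation.
#' @export
validate_gaze_recording <- function(rec) {
  stopifnot(inherits(rec, "gaze_recording"))
  if (!is.finite(rec$nominal_rate) || rec$nominal_rate <= 0) {
    abort("nominal_rate must be a positive finite number")
  }
  s <- rec$samples
  if (nrow(s) > 0) {
    if (any(!is.finite(s$t)) || any(s$t < 0)) {
      abort("sample timestamps must be finite and non-negative")
    }
    bad <- vapply(split(s$t, s$trial), function(tt) any(diff(tt) <= 0),
                  logical(1))
    if (any(bad)) {
      abort(sprintf(
        "sample timestamps must be strictly increasing within a trial (trial %s)",
        names(bad)[which(bad)[1]]))
    }
  }
  m <- rec$messages
  if (nrow(m) > 0) {
    badm <- vapply(split(m$t, m$trial), function(tt) any(diff(tt) < 0),
                   logical(1))
    if (any(badm)) {
      abort(sprintf(
        "message timestamps must be nondecreasing within a trial (trial %s)",
        names(badm)[which(badm)[1]]))
    }
  }
  rec
}

#' @export
print.gaze_recording <- function(x, ...) {
  nt <- length(unique(x$samples$trial))
  cat(sprintf(
    "<gaze_recording> %d trial(s), %d samples (%.1f%% valid), %d messages, %g Hz nominal\n",
    nt, nrow(x$samples),
    if (nrow(x$samples)) 100 * mean(x$samples$valid) else 100,
    nrow(x$messages), x$nominal_rate))
  invisible(x)
}

#' Trial indices present in a recording
#' @param rec A `gaze_recording`.
#' @return Sorted integer vector of trial indices.
#' @export
trial_indices <- function(rec) {
  stopifnot(inherits(rec, "gaze_recording"))
  sort(unique(c(rec$samples$trial, rec$messages$trial)))
}

#' Extract one trial from a recording
#'
#' @param rec A `gaze_recording`.
#' @param index Trial index.
#' @return List with tibbles `samples` and `messages` for that trial.
#' @export
get_trial <- function(rec, index) {
  stopifnot(inherits(rec, "gaze_recording"))
  list(samples = rec$samples[rec$samples$trial == index, ],
       messages = rec$messages[rec$messages$trial == index, ])
}

#' Per-trial intersample-interval statistics
#'
#' Summarises the distribution of consecutive timestamp differences within
#' each trial. The intersample-interval distribution is the standard
#' diagnostic for recorder timing: its spread reveals timestamp jitter, and
#' intervals near twice the nominal interval reveal frame loss. Intervals
#' are computed over all samples, valid and invalid alike (tracking loss
#' does not interrupt the camera clock). Percentiles use linear
#' interpolation between order statistics (R quantile type 7).
#'
#' @param data A `gaze_recording` or a samples data frame with columns
#'   `trial` and `t`.
#' @return A tibble with one row per trial: `trial`, `n_intervals`, `mean`,
#'   `sd`, `p0_5`, `p99_5`, `min`, `max` (all in ms).
#' @examples
#' rec <- gaze_recording(
#'   data.frame(trial = 1L, t = c(0, 8, 17, 25), x = 0, y = 0, valid = TRUE),
#'   nominal_rate = 120
#' )
#' intersample_stats(rec)
#' @export
intersample_stats <- function(data) {
  s <- if (inherits(data, "gaze_recording")) data$samples else
    tibble::as_tibble(as.data.frame(data))
  stopifnot(all(c("trial", "t") %in% names(s)))
  too_few <- table(s$trial) < 2
  if (any(too_few)) {
    abort(sprintf("trial %s has fewer than 2 samples",
                  names(too_few)[which(too_few)[1]]))
  }
  s |>
    dplyr::group_by(trial = .data$trial) |>
    dplyr::summarise(
      n_intervals = dplyr::n() - 1L,
      mean = mean(diff(.data$t)),
      sd = stats::sd(diff(.data$t)),
      p0_5 = unname(stats::quantile(diff(.data$t), 0.005, type = 7)),
      p99_5 = unname(stats::quantile(diff(.data$t), 0.995, type = 7)),
      min = min(diff(.data$t)),
      max = max(diff(.data$t)),
      .groups = "drop"
    )
}
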