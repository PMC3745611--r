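#' First saccade at or after a reference time
#'
#' Returns the earliest saccade whose onset is at or after `t0` (closed
#' lower boundary: a saccade starting exactly at `t0` counts).
#'
#' @param events A `gaze_events` tibble (one trial).
#' @param t0 Reference time, ms (e.g. a target-onset message timestamp).
#' @return One-row tibble (the saccade) or a zero-row tibble if none.
#' @export
first_saccade_after <- function(events, t0) {
  sac <- events[events$event == "saccade" & events$onset >= t0, ]
  sac <- dplyr::arrange(sac, .data$onset)
  sac[seq_len(min(1, nrow(sac))), ]
}

#' Saccade latency relative to a message
#'
#' Onset time of the saccade minus the message timestamp, ms.
#'
#' @param saccade One-row saccade tibble (with column `onset`).
#' @param t_msg Message timestamp, ms.
#' @return Latency in ms.
#' @export
saccade_latency <- function(saccade, t_msg) {
  saccade$onset - t_msg
}

#' Classify a single trial of a saccade task
#'
#' A trial is valid iff (1) a first saccade exists at or after target
#' onset, (2) it is not flagged unreliable by a tracking-loss gap, (3) its
#' latency lies in the closed window `latency_window` (default 100-600 ms),
#' and (4) its end point lands within `landing_radius` (default 2.0 deg) of
#' the expected position — the target itself for prosaccades, the mirror
#' position for antisaccades. Invalid trials carry one rejection reason,
#' checked in the order `no_saccade`, `detection_gap`,
#' `latency_out_of_range`, `landing_too_far`.
#'
#' @param events `gaze_events` for one trial.
#' @param target_onset Target onset time, ms.
#' @param expected Numeric `(x, y)`: expected landing position, deg.
#' @param latency_window Closed latency window, ms.
#' @param landing_radius Maximum distance from expected landing, deg.
#' @return One-row tibble: `latency`, `amplitude`, `land_x`, `land_y`,
#'   `valid`, `rejection_reason` (NA when valid).
#' @export
classify_trial <- function(events, target_onset, expected,
                           latency_window = c(100, 600),
                           landing_radius = 2.0) {
  out <- tibble::tibble(latency = NA_real_, amplitude = NA_real_,
                        land_x = NA_real_, land_y = NA_real_,
                        valid = FALSE, rejection_reason = NA_character_)
  sac <- first_saccade_after(events, target_onset)
  if (nrow(sac) == 0) {
    out$rejection_reason <- "no_saccade"
    return(out)
  }
  out$latency <- sac$onset - target_onset
  out$amplitude <- sac$amplitude
  out$land_x <- sac$x1
  out$land_y <- sac$y1
  if (isTRUE(sac$unreliable)) {
    out$rejection_reason <- "detection_gap"
  } else if (out$latency < latency_window[1] ||
             out$latency > latency_window[2]) {
    out$rejection_reason <- "latency_out_of_range"
  } else if (sqrt((sac$x1 - expected[[1]])^2 +
                  (sac$y1 - expected[[2]])^2) > landing_radius) {
    out$rejection_reason <- "landing_too_far"
  } else {
    out$valid <- TRUE
  }
  out
}

# pull "<KEY> x y" payload from one trial's messages; NULL if absent
msg_payload <- function(messages, key) {
  hit <- messages[startsWith(messages$text, paste0(key, " ")), ]
  if (nrow(hit) == 0) return(NULL)
  parts <- strsplit(hit$text[1], " ", fixed = TRUE)[[1]]
  list(t = hit$t[1], value = suppressWarnings(as.numeric(parts[-1])),
       label = paste(parts[-1], collapse = " "))
}

#' Classify every trial of a recorded session
#'
#' Applies [classify_trial()] across a recording, reading each trial's
#' condition, target onset and expected landing from its messages
#' (`COND <label>`, `TARGET_ON x y`, `EXPECT x y` — the message layout
#' written by [simulate_session()]). Trials missing a target message or
#' with no detected events are classified invalid with reason `no_saccade`.
#'
#' @param rec A [gaze_recording()].
#' @param events A `gaze_events` tibble with a `trial` column (from
#'   [detect_session()]).
#' @inheritParams classify_trial
#' @return A tibble with one row per trial: `trial`, `condition`, then the
#'   [classify_trial()] columns.
#' @export
classify_session <- function(rec, events, latency_window = c(100, 600),
                             landing_radius = 2.0) {
  stopifnot(inherits(rec, "gaze_recording"))
  purrr::map_dfr(trial_indices(rec), function(i) {
    msgs <- rec$messages[rec$messages$trial == i, ]
    cond <- msg_payload(msgs, "COND")
    tgt <- msg_payload(msgs, "TARGET_ON")
    exp <- msg_payload(msgs, "EXPECT")
    base <- tibble::tibble(trial = i,
                           condition = if (is.null(cond)) NA_character_
                           else cond$label)
    ev <- events[events$trial == i, ]
    if (is.null(tgt) || nrow(ev) == 0) {
      return(dplyr::bind_cols(base, tibble::tibble(
        latency = NA_real_, amplitude = NA_real_, land_x = NA_real_,
        land_y = NA_real_, valid = FALSE, rejection_reason = "no_saccade")))
    }
    expected <- if (is.null(exp)) tgt$value else exp$value
    dplyr::bind_cols(base, classify_trial(ev, tgt$t, expected,
                                          latency_window, landing_radius))
  })
}

#' Spatial accuracy around target jumps
#'
#' For each target jump, computes the mean Euclidean distance between the
#' valid gaze samples recorded strictly within `(t_jump + window[1],
#' t_jump + window[2])` ms (default 250-750 ms, i.e. after the orienting
#' saccade has landed and before the next jump) and the target position.
#' Jumps whose window contains no valid sample are skipped and reported
#' with `n = 0`.
#'
#' @param samples One trial's samples: columns `t`, `x`, `y`, `valid`.
#' @param jumps Data frame of target jumps: columns `t`, `x`, `y`.
#' @param window Length-2 offsets after each jump, ms (open interval).
#' @return List with `per_jump` (tibble: `t_jump`, `n`, `mean_error`) and
#'   `overall` (mean over jumps with data, deg).
#' @export
spatial_error <- function(samples, jumps, window = c(250, 750)) {
  samples <- as.data.frame(samples)
  jumps <- as.data.frame(jumps)
  stopifnot(all(c("t", "x", "y", "valid") %in% names(samples)),
            all(c("t", "x", "y") %in% names(jumps)))
  per <- purrr::map_dfr(seq_len(nrow(jumps)), function(i) {
    sel <- samples$valid & samples$t > jumps$t[i] + window[1] &
      samples$t < jumps$t[i] + window[2]
    err <- sqrt((samples$x[sel] - jumps$x[i])^2 +
                  (samples$y[sel] - jumps$y[i])^2)
    tibble::tibble(t_jump = jumps$t[i], n = sum(sel),
                   mean_error = if (sum(sel)) mean(err) else NA_real_)
  })
  list(per_jump = per,
       overall = mean(per$mean_error[per$n > 0]))
}

#' Summarise a classified saccade task
#'
#' Per-condition means and SDs of latency and amplitude over valid trials,
#' plus the overall fraction of removed (invalid) trials.
#'
#' @param outcomes Tibble from [classify_session()] (or hand-built, with
#'   columns `condition`, `latency`, `amplitude`, `valid`).
#' @return An object of class `gaze_task_summary`; `tidy()` returns the
#'   per-condition table, `glance()` the one-row overall summary.
#' @export
summarize_task <- function(outcomes) {
  outcomes <- tibble::as_tibble(as.data.frame(outcomes))
  stopifnot(all(c("condition", "latency", "amplitude", "valid") %in%
                  names(outcomes)))
  by_cond <- outcomes |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(condition = .data$condition) |>
    dplyr::summarise(n_valid = dplyr::n(),
                     mean_latency = mean(.data$latency),
                     sd_latency = stats::sd(.data$latency),
                     mean_amplitude = mean(.data$amplitude),
                     sd_amplitude = stats::sd(.data$amplitude),
                     .groups = "drop")
  structure(list(by_condition = by_cond,
                 n_trials = nrow(outcomes),
                 n_valid = sum(outcomes$valid),
                 removal_fraction = 1 - sum(outcomes$valid) /
                   nrow(outcomes)),
            class = "gaze_task_summary")
}

#' @export
print.gaze_task_summary <- function(x, ...) {
  cat(sprintf("<gaze_task_summary> %d trials, %d valid (%.1f%% removed)\n",
              x$n_trials, x$n_valid, 100 * x$removal_fraction))
  print(x$by_condition)
  invisible(x)
}

#' @describeIn summarize_task Per-condition summary tibble.
#' @param x A `gaze_task_summary`.
#' @param ... Unused.
#' @export
tidy.gaze_task_summary <- function(x, ...) x$by_condition

#' @describeIn summarize_task One-row overall summary.
#' @export
glance.gaze_task_summary <- function(x, ...) {
  tibble::tibble(n_trials = x$n_trials, n_valid = x$n_valid,
                 removal_fraction = x$removal_fraction)
}
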