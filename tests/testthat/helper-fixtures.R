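# Fixture builders shared across tests. Everything is generated in code.

# Trial whose supra-threshold pattern is exactly `pattern` (logical/0-1):
# positions are irrelevant placeholders; the matching speed series is
# injected into detect_events() via its `speed` argument.
pattern_trial <- function(pattern, delta_ms = 4, velocity_threshold = 22) {
  n <- length(pattern)
  list(
    samples = data.frame(t = (seq_len(n) - 1) * delta_ms,
                         x = cumsum(as.numeric(pattern)) * 0.2, y = 0,
                         valid = TRUE),
    speed = ifelse(as.logical(pattern), velocity_threshold + 10,
                   velocity_threshold - 10)
  )
}

# Random small recording for round-trip property tests: jittered
# timestamps, tracking loss, messages containing commas and odd floats.
random_recording <- function(n_trials = 3, seed = 1) {
  withr::with_seed(seed, {
    samples <- dplyr::bind_rows(lapply(seq_len(n_trials), function(i) {
      n <- sample(5:40, 1)
      data.frame(trial = i,
                 t = cumsum(runif(n, 0.5, 12)),
                 x = rnorm(n, 0, 5), y = rnorm(n, 0, 5),
                 valid = runif(n) > 0.15)
    }))
    messages <- dplyr::bind_rows(lapply(seq_len(n_trials), function(i) {
      data.frame(trial = i, t = sort(runif(2, 0, 100)),
                 text = c("TARGET_ON 1.5 -2.25", "note, with commas, ok"))
    }))
    gaze_recording(samples, messages, nominal_rate = 120,
                   geometry = screen_geometry(57, 28.4, c(1024, 768)))
  })
}

# Crafted 40-trial classification fixture with 6 planted violations:
# trials 3 and 9 latency below 100 ms, trial 15 latency above 600 ms,
# trials 21 and 30 landing more than 2 deg off, trial 36 overlapping a
# tracking-loss gap. Returns list(recording, events, planted).
crafted_classification_fixture <- function() {
  n <- 40
  target <- c(4.2, 0)
  latency <- rep(200, n)
  latency[c(3, 9)] <- c(80, 95)
  latency[15] <- 650
  land <- matrix(rep(c(4.2, 0.3), n), ncol = 2, byrow = TRUE)
  land[21, ] <- c(4.2, 2.8)   # 2.5 deg from target
  land[30, ] <- c(1.2, 0.0)   # 3.0 deg from target
  unreliable <- rep(FALSE, n)
  unreliable[36] <- TRUE
  target_on <- 1000

  samples <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    data.frame(trial = i, t = c(0, 10), x = 0, y = 0, valid = TRUE)
  }))
  messages <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    data.frame(trial = i, t = c(0, target_on, target_on),
               text = c("COND prosaccade",
                        sprintf("TARGET_ON %g %g", target[1], target[2]),
                        sprintf("EXPECT %g %g", target[1], target[2])))
  }))
  rec <- gaze_recording(samples, messages, nominal_rate = 250)

  events <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    onset <- target_on + latency[i]
    tibble::tibble(trial = i, event = "saccade", onset = onset,
                   offset = onset + 30, duration = 30, x0 = 0, y0 = 0,
                   x1 = land[i, 1], y1 = land[i, 2],
                   amplitude = sqrt(sum(land[i, ]^2)),
                   peak_velocity = 300, cx = NA_real_, cy = NA_real_,
                   unreliable = unreliable[i])
  }))
  planted <- tibble::tibble(
    trial = c(3, 9, 15, 21, 30, 36),
    reason = c("latency_out_of_range", "latency_out_of_range",
               "latency_out_of_range", "landing_too_far",
               "landing_too_far", "detection_gap"))
  list(recording = rec, events = events, planted = planted)
}

# Compare detected saccades against simulator ground truth: for each true
# saccade, the detected saccade whose onset is nearest. Returns a tibble
# with one row per true saccade (onset/amplitude errors, NA if no
# detection within `max_onset_err` ms).
match_detections <- function(truth, events, max_onset_err) {
  sac <- events[events$event == "saccade", ]
  purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    cand <- sac[sac$trial == tr$trial, ]
    if (nrow(cand) == 0) {
      return(tibble::tibble(trial = tr$trial, detected = FALSE,
                            onset_err = NA_real_, amp_err = NA_real_))
    }
    j <- which.min(abs(cand$onset - tr$t_onset))
    onset_err <- cand$onset[j] - tr$t_onset
    tibble::tibble(trial = tr$trial,
                   detected = abs(onset_err) <= max_onset_err,
                   onset_err = onset_err,
                   amp_err = cand$amplitude[j] - tr$amplitude)
  })
}
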