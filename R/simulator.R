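#' Construct a calibration model from known coefficients
#'
#' Builds a `gaze_calibration` object directly from the six mapping
#' coefficients (degrees-per-pixel gains and degree offsets). Used by the
#' simulator as the ground-truth camera-to-screen mapping. The 2 x 2 gain
#' matrix must be nonsingular for the model to be invertible.
#'
#' @param a_X,b_X,c_X,a_Y,b_Y,c_Y Model coefficients of
#'   `X = aX*U + bX*V + cX`, `Y = aY*U + bY*V + cY`.
#' @return A `gaze_calibration` object.
#' @export
calibration_model <- function(a_X, b_X, c_X, a_Y, b_Y, c_Y) {
  coefs <- c(a_X = a_X, b_X = b_X, c_X = c_X,
             a_Y = a_Y, b_Y = b_Y, c_Y = c_Y)
  stopifnot(all(is.finite(coefs)))
  structure(list(coefficients = coefs, sse = NA_real_, n = 0L,
                 per_target = NULL),
            class = "gaze_calibration")
}

#' Draw a random nonsingular calibration model
#'
#' Gains are drawn uniformly with magnitudes typical of a desktop
#' pupil/corneal-reflection setup (roughly 0.05-0.4 deg/px on the diagonal,
#' small cross-coupling) and redrawn until the gain matrix determinant is
#' comfortably away from zero. Uses the ambient RNG stream.
#'
#' @return A `gaze_calibration` object.
#' @export
random_calibration_model <- function() {
  repeat {
    m <- calibration_model(
      a_X = runif(1, 0.05, 0.4) * sample(c(-1, 1), 1),
      b_X = runif(1, -0.1, 0.1),
      c_X = runif(1, -5, 5),
      a_Y = runif(1, -0.1, 0.1),
      b_Y = runif(1, 0.05, 0.4) * sample(c(-1, 1), 1),
      c_Y = runif(1, -5, 5))
    cf <- m$coefficients
    if (abs(cf["a_X"] * cf["b_Y"] - cf["b_X"] * cf["a_Y"]) > 1e-3) return(m)
  }
}

#' Simulation configuration
#'
#' All generative parameters of a synthetic eye-tracking session. Defaults
#' reproduce the study conditions of the tasks they emulate: 4.2 deg target
#' eccentricity, fixation durations drawn from 1000-1500 ms in 100-ms
#' steps, gap durations -200..200 ms balanced within blocks, 20 trials per
#' block, detection-relevant fixation noise of 0.1 deg, and a raised-cosine
#' saccade velocity profile with main-sequence duration
#' `D = d0 + d1 * amplitude` (20 ms + 2 ms/deg). Latency distributions are
#' truncated normal on [80, 700] ms; per-condition means/SDs can be
#' overridden via `latency_model`.
#'
#' @param task `"gapoverlap"`, `"antisaccade"` or `"grid"` (the 6 x 6,
#'   2.7-deg-spacing accuracy-test task with 10 target jumps per trial).
#' @param nominal_rate Sampling rate, Hz (one of 120, 250, 400, 500).
#' @param trials_per_block,blocks Trial counts. For the antisaccade task,
#'   block types alternate prosaccade/antisaccade.
#' @param fixation_noise_sd Isotropic positional noise SD, deg.
#' @param timestamp_jitter_sd SD of intersample-interval jitter, ms.
#' @param frame_drop_prob Per-sample i.i.d. probability of a lost frame.
#' @param gap_prob Per-sample probability of entering a tracking-loss gap
#'   (two-state Markov model).
#' @param gap_dur_ms Mean tracking-loss gap duration, ms.
#' @param latency_model Optional data frame overriding the per-condition
#'   latency model: columns `condition`, `mean`, `sd`.
#' @param kinematics List with `d0_ms` and `d1_ms_per_deg` of the
#'   duration-amplitude rule.
#' @param landing_noise_sd SD of isotropic landing scatter, deg.
#' @param target_eccentricity Target distance from fixation, deg.
#' @param seed Integer seed; mandatory, every stochastic output derives
#'   from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(task = c("gapoverlap", "antisaccade", "grid"),
                       nominal_rate = 250, trials_per_block = 20,
                       blocks = 1, fixation_noise_sd = 0.1,
                       timestamp_jitter_sd = 0, frame_drop_prob = 0,
                       gap_prob = 0, gap_dur_ms = 100,
                       latency_model = NULL,
                       kinematics = list(d0_ms = 20, d1_ms_per_deg = 2),
                       landing_noise_sd = 0.3, target_eccentricity = 4.2,
                       seed) {
  task <- match.arg(task)
  if (missing(seed)) abort("sim_config requires an explicit seed")
  stopifnot(nominal_rate > 0, trials_per_block > 0, blocks > 0,
            fixation_noise_sd >= 0, timestamp_jitter_sd >= 0,
            frame_drop_prob >= 0, frame_drop_prob < 1,
            gap_prob >= 0, gap_prob < 1, gap_dur_ms > 0,
            landing_noise_sd >= 0, target_eccentricity > 0)
  if (is.null(latency_model)) {
    latency_model <- switch(task,
      gapoverlap = tibble::tibble(
        condition = paste0("gap", c(-200, -100, 0, 100, 200)),
        mean = c(150, 175, 200, 230, 260), sd = 50),
      antisaccade = tibble::tibble(
        condition = c("prosaccade", "antisaccade"),
        mean = c(200, 270), sd = 50),
      grid = tibble::tibble(condition = "grid", mean = 150, sd = 20))
  }
  structure(
    list(task = task, nominal_rate = nominal_rate,
         trials_per_block = trials_per_block, blocks = blocks,
         fixation_noise_sd = fixation_noise_sd,
         timestamp_jitter_sd = timestamp_jitter_sd,
         frame_drop_prob = frame_drop_prob, gap_prob = gap_prob,
         gap_dur_ms = gap_dur_ms,
         latency_model = tibble::as_tibble(latency_model),
         kinematics = kinematics, landing_noise_sd = landing_noise_sd,
         target_eccentricity = target_eccentricity,
         latency_range = c(80, 700), seed = as.integer(seed)),
    class = "sim_config")
}

#' Saccade kinematics: duration and raised-cosine profile
#'
#' The simulator uses a raised-cosine velocity profile: for normalized time
#' `u = (t - onset) / D` in [0, 1], velocity is proportional to
#' `1 - cos(2*pi*u)` and the displaced fraction of the amplitude is
#' `u - sin(2*pi*u) / (2*pi)`. Peak velocity is exactly
#' `2 * amplitude / D`. Duration follows the linear main-sequence rule
#' `D = d0 + d1 * amplitude`.
#'
#' @param amplitude Saccade amplitude, deg.
#' @param d0_ms,d1_ms_per_deg Main-sequence intercept and slope.
#' @return `saccade_duration`: duration in ms.
#' @export
saccade_duration <- function(amplitude, d0_ms = 20, d1_ms_per_deg = 2) {
  d0_ms + d1_ms_per_deg * amplitude
}

#' @rdname saccade_duration
#' @param u Normalized time in [0, 1] (values outside are clamped).
#' @return `saccade_progress`: displaced fraction of the amplitude in
#'   [0, 1]; `saccade_velocity`: velocity in deg/s for the given amplitude
#'   (deg) and duration (ms).
#' @export
saccade_progress <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u - sin(2 * pi * u) / (2 * pi)
}

#' @rdname saccade_duration
#' @param duration_ms Saccade duration, ms.
#' @export
saccade_velocity <- function(u, amplitude, duration_ms) {
  u <- pmin(pmax(u, 0), 1)
  (amplitude / duration_ms) * (1 - cos(2 * pi * u)) * 1000
}

# truncated-normal draw by rejection (bounds guaranteed by construction)
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

unit_dir <- function(name) {
  switch(name,
         right = c(1, 0), left = c(-1, 0), up = c(0, 1), down = c(0, -1))
}

schedule_impl <- function(cfg) {
  n <- cfg$trials_per_block
  fix_choices <- seq(1000, 1500, by = 100)
  if (cfg$task == "gapoverlap") {
    gaps <- c(-200, -100, 0, 100, 200)
    combos <- tidyr::expand_grid(gap = gaps, direction = c("left", "right"))
    if (n %% nrow(combos) != 0) {
      abort("trials_per_block must be a multiple of 10 for gapoverlap")
    }
    per_block <- function(b) {
      d <- combos[rep(seq_len(nrow(combos)), n / nrow(combos)), ]
      d <- d[sample.int(nrow(d)), ]
      d$block <- b
      d$condition <- paste0("gap", d$gap)
      d
    }
    sched <- dplyr::bind_rows(lapply(seq_len(cfg$blocks), per_block))
    sched$fix_dur <- sample(fix_choices, nrow(sched), replace = TRUE)
    sched$t_fix_off <- sched$fix_dur
    # negative gap: fixation off before target on (gap condition)
    sched$t_target_on <- sched$t_fix_off - sched$gap
    sched$t_end <- 3000
  } else if (cfg$task == "antisaccade") {
    block_type <- rep(c("prosaccade", "antisaccade"),
                      length.out = cfg$blocks)
    dirs <- c("left", "right", "up", "down")
    if (n %% length(dirs) != 0) {
      abort("trials_per_block must be a multiple of 4 for antisaccade")
    }
    per_block <- function(b) {
      d <- tibble::tibble(direction = rep(dirs, n / length(dirs)))
      d <- d[sample.int(nrow(d)), , drop = FALSE]
      d$block <- b
      d$condition <- block_type[b]
      d$gap <- NA_real_
      d
    }
    sched <- dplyr::bind_rows(lapply(seq_len(cfg$blocks), per_block))
    sched$fix_dur <- sample(fix_choices, nrow(sched), replace = TRUE)
    sched$t_fix_off <- sched$fix_dur
    sched$t_target_on <- sched$t_fix_off
    sched$t_end <- 3000
  } else { # grid
    pos <- grid_positions(6, 6, 2.7, 2.7)
    per_block <- function(b) {
      tibble::tibble(block = b, condition = "grid", gap = NA_real_,
                     direction = NA_character_,
                     fix_dur = NA_real_, t_fix_off = NA_real_,
                     t_target_on = NA_real_, t_end = 11000,
                     jumps = lapply(seq_len(n), function(i) {
                       nodes <- pos[sample.int(nrow(pos), 10), ]
                       tibble::tibble(t = 1000 * seq_len(10),
                                      x = nodes$x, y = nodes$y)
                     }))
    }
    sched <- dplyr::bind_rows(lapply(seq_len(cfg$blocks), per_block))
  }
  sched$trial <- seq_len(nrow(sched))
  ecc <- cfg$target_eccentricity
  if (cfg$task != "grid") {
    dxy <- t(vapply(sched$direction, unit_dir, numeric(2)))
    sched$target_x <- unname(ecc * dxy[, 1])
    sched$target_y <- unname(ecc * dxy[, 2])
    mirror <- ifelse(sched$condition == "antisaccade", -1, 1)
    sched$expect_x <- mirror * sched$target_x
    sched$expect_y <- mirror * sched$target_y
  }
  tibble::as_tibble(sched)
}

#' Generate a task schedule
#'
#' Builds the trial-by-trial schedule for the configured task: conditions
#' balanced within each block (directions and gap durations), randomized
#' orders, fixation durations drawn from 1000-1500 ms, target onset times
#' and target/expected-landing positions. For the antisaccade task the
#' expected landing is the mirror of the target about the fixation point.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with one row per trial.
#' @export
make_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, schedule_impl(cfg))
}

# draw a latency for a condition label
draw_latency <- function(cfg, condition, n = 1) {
  row <- cfg$latency_model[cfg$latency_model$condition == condition, ]
  if (nrow(row) != 1) abort(sprintf("no latency model for '%s'", condition))
  rtruncnorm1(n, row$mean, row$sd, cfg$latency_range[1], cfg$latency_range[2])
}

# sample a timestamp grid: jittered intervals, cumulative, then frame drops
sample_times <- function(cfg, t_end) {
  delta <- 1000 / cfg$nominal_rate
  n <- ceiling(t_end / delta) + 1L
  iv <- rep(delta, n - 1L)
  if (cfg$timestamp_jitter_sd > 0) {
    iv <- pmax(iv + rnorm(n - 1L, 0, cfg$timestamp_jitter_sd), 0.1 * delta)
  }
  t <- c(0, cumsum(iv))
  t <- t[t <= t_end]
  if (cfg$frame_drop_prob > 0) {
    keep <- c(TRUE, runif(length(t) - 1L) >= cfg$frame_drop_prob)
    t <- t[keep]
  }
  t
}

# two-state Markov tracking-loss process over a sample grid
sample_validity <- function(cfg, n, delta) {
  if (cfg$gap_prob == 0 || n == 0) return(rep(TRUE, n))
  p_exit <- min(delta / cfg$gap_dur_ms, 1)
  valid <- logical(n)
  state <- TRUE
  u <- runif(n)
  for (i in seq_len(n)) {
    state <- if (state) u[i] >= cfg$gap_prob else u[i] < p_exit
    valid[i] <- state
  }
  valid
}

# simulate one trial; returns list(samples, messages, truth)
synth_trial <- function(sr, cfg) {
  t <- sample_times(cfg, sr$t_end)
  n <- length(t)
  delta <- 1000 / cfg$nominal_rate
  if (cfg$task == "grid") {
    jumps <- sr$jumps[[1]]
    starts_x <- c(0, jumps$x[-nrow(jumps)])
    starts_y <- c(0, jumps$y[-nrow(jumps)])
    lat <- draw_latency(cfg, "grid", nrow(jumps))
    segs <- tibble::tibble(
      t_target_on = jumps$t, target_x = jumps$x, target_y = jumps$y,
      expect_x = jumps$x, expect_y = jumps$y,
      start_x = starts_x, start_y = starts_y, latency = lat)
  } else {
    segs <- tibble::tibble(
      t_target_on = sr$t_target_on, target_x = sr$target_x,
      target_y = sr$target_y, expect_x = sr$expect_x,
      expect_y = sr$expect_y, start_x = 0, start_y = 0,
      latency = draw_latency(cfg, sr$condition))
  }
  k <- nrow(segs)
  segs$land_x <- segs$expect_x + rnorm(k, 0, cfg$landing_noise_sd)
  segs$land_y <- segs$expect_y + rnorm(k, 0, cfg$landing_noise_sd)
  # landings chain for multi-jump trials
  if (k > 1) {
    segs$start_x <- c(0, segs$land_x[-k])
    segs$start_y <- c(0, segs$land_y[-k])
  }
  segs$amplitude <- sqrt((segs$land_x - segs$start_x)^2 +
                           (segs$land_y - segs$start_y)^2)
  segs$duration <- saccade_duration(segs$amplitude, cfg$kinematics$d0_ms,
                                    cfg$kinematics$d1_ms_per_deg)
  segs$t_onset <- segs$t_target_on + segs$latency
  segs$t_offset <- segs$t_onset + segs$duration
  # keep successive movements separated; resample latencies that collide
  if (k > 1) {
    for (i in 2:k) {
      tries <- 0
      while (segs$t_onset[i] <= segs$t_offset[i - 1] + 2 * delta &&
             tries < 100) {
        segs$latency[i] <- draw_latency(cfg, "grid")
        segs$t_onset[i] <- segs$t_target_on[i] + segs$latency[i]
        segs$t_offset[i] <- segs$t_onset[i] + segs$duration[i]
        tries <- tries + 1
      }
    }
  }
  x <- rep(segs$start_x[1], n)
  y <- rep(segs$start_y[1], n)
  for (i in seq_len(k)) {
    sel <- t >= segs$t_onset[i]
    u <- (t[sel] - segs$t_onset[i]) / segs$duration[i]
    p <- saccade_progress(u)
    x[sel] <- segs$start_x[i] + (segs$land_x[i] - segs$start_x[i]) * p
    y[sel] <- segs$start_y[i] + (segs$land_y[i] - segs$start_y[i]) * p
  }
  if (cfg$fixation_noise_sd > 0) {
    x <- x + rnorm(n, 0, cfg$fixation_noise_sd)
    y <- y + rnorm(n, 0, cfg$fixation_noise_sd)
  }
  valid <- sample_validity(cfg, n, delta)
  samples <- tibble::tibble(trial = sr$trial, t = t, x = x, y = y,
                            valid = valid)
  msgs <- list(tibble::tibble(trial = sr$trial, t = 0,
                              text = paste("COND", sr$condition)))
  if (cfg$task != "grid") {
    msgs <- c(msgs, list(
      tibble::tibble(trial = sr$trial, t = 0, text = "FIX_ON"),
      tibble::tibble(trial = sr$trial, t = sr$t_fix_off, text = "FIX_OFF")))
  }
  msgs <- c(msgs, list(
    tibble::tibble(trial = sr$trial, t = segs$t_target_on,
                   text = sprintf("TARGET_ON %.6f %.6f", segs$target_x,
                                  segs$target_y)),
    tibble::tibble(trial = sr$trial, t = segs$t_target_on,
                   text = sprintf("EXPECT %.6f %.6f", segs$expect_x,
                                  segs$expect_y))))
  messages <- dplyr::arrange(dplyr::bind_rows(msgs), .data$t)
  truth <- dplyr::bind_cols(
    tibble::tibble(trial = sr$trial, condition = sr$condition,
                   gap = if ("gap" %in% names(sr)) sr$gap else NA_real_),
    segs[c("t_target_on", "target_x", "target_y", "expect_x", "expect_y",
           "latency", "t_onset", "t_offset", "amplitude",
           "land_x", "land_y")])
  list(samples = samples, messages = messages, truth = truth)
}

#' Simulate a complete synthetic session
#'
#' Generates the full session for a [sim_config()]: schedule, per-trial
#' gaze traces (fixations with isotropic Gaussian noise, raised-cosine
#' saccades with per-condition latencies, timestamp jitter, frame drops and
#' tracking-loss gaps), interleaved messages (`COND`, `FIX_ON`, `FIX_OFF`,
#' `TARGET_ON x y`, `EXPECT x y`), and the generative ground truth for
#' every saccade. Bit-identical output for identical configuration and
#' seed.
#'
#' @param cfg A [sim_config()].
#' @param geometry Optional [screen_geometry()] stored in the recording.
#' @return A list of class `gaze_session`: `recording` (a
#'   [gaze_recording()]), `truth` (tibble, one row per injected saccade)
#'   and `schedule`.
#' @export
simulate_session <- function(cfg, geometry = screen_geometry()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    sched <- schedule_impl(cfg)
    parts <- lapply(seq_len(nrow(sched)), function(i) {
      synth_trial(sched[i, ], cfg)
    })
  })
  rec <- gaze_recording(
    dplyr::bind_rows(lapply(parts, `[[`, "samples")),
    dplyr::bind_rows(lapply(parts, `[[`, "messages")),
    nominal_rate = cfg$nominal_rate, geometry = geometry)
  structure(list(recording = rec,
                 truth = dplyr::bind_rows(lapply(parts, `[[`, "truth")),
                 schedule = sched),
            class = "gaze_session")
}

#' @export
print.gaze_session <- function(x, ...) {
  cat(sprintf("<gaze_session> %s task, %d trials, %d true saccades\n",
              x$schedule$condition[1], nrow(x$schedule), nrow(x$truth)))
  print(x$recording)
  invisible(x)
}

#' Invert a calibration model: gaze to feature space
#'
#' Maps screen gaze `(x, y)` back through a nonsingular calibration model
#' to the camera-pixel feature vector `(U, V)`, optionally adding Gaussian
#' camera-pixel noise. Feeding the result through
#' [select_calibration_samples()]/[fit_calibration()]/[predict()] recovers
#' the gaze trace, which closes the calibration loop end to end.
#'
#' @param samples Data frame with columns `t`, `x`, `y` (and optionally
#'   `valid`; invalid samples yield NA features).
#' @param model A `gaze_calibration` with nonsingular gain matrix.
#' @param pixel_noise_sd Additive noise SD on U and V, px.
#' @return Tibble with columns `t`, `U`, `V`.
#' @export
synth_feature_stream <- function(samples, model, pixel_noise_sd = 0) {
  stopifnot(inherits(model, "gaze_calibration"))
  cf <- model$coefficients
  det <- cf["a_X"] * cf["b_Y"] - cf["b_X"] * cf["a_Y"]
  if (abs(det) < 1e-12) abort("calibration model is singular")
  samples <- as.data.frame(samples)
  rx <- samples$x - cf["c_X"]
  ry <- samples$y - cf["c_Y"]
  U <- (cf["b_Y"] * rx - cf["b_X"] * ry) / det
  V <- (-cf["a_Y"] * rx + cf["a_X"] * ry) / det
  if (pixel_noise_sd > 0) {
    U <- U + rnorm(length(U), 0, pixel_noise_sd)
    V <- V + rnorm(length(V), 0, pixel_noise_sd)
  }
  if ("valid" %in% names(samples)) {
    U[!samples$valid] <- NA_real_
    V[!samples$valid] <- NA_real_
  }
  tibble::tibble(t = samples$t, U = U, V = V)
}

#' Simulate a calibration sample stream
#'
#' Generates the feature-space stream recorded while a simulated eye
#' tracks the calibration target: gaze follows the schedule (dwelling on
#' each position, moving linearly during travel periods) with isotropic
#' positional noise, and is mapped to `(U, V)` through the inverse of the
#' true model, with optional camera-pixel noise.
#'
#' @param model True `gaze_calibration` model.
#' @param schedule A [calibration_schedule()].
#' @param rate_hz Sampling rate, Hz.
#' @param gaze_noise_sd Isotropic gaze noise SD, deg.
#' @param pixel_noise_sd Feature noise SD, px.
#' @return Tibble with columns `t`, `U`, `V`.
#' @export
simulate_calibration_stream <- function(model, schedule, rate_hz = 250,
                                        gaze_noise_sd = 0,
                                        pixel_noise_sd = 0) {
  stopifnot(inherits(schedule, "calibration_schedule"))
  t_end <- max(schedule$t_depart)
  t <- seq(0, t_end - 1e-9, by = 1000 / rate_hz)
  i <- pmax(findInterval(t, schedule$t_move), 1L)
  gx <- schedule$x[i]
  gy <- schedule$y[i]
  moving <- t < schedule$t_arrive[i] & i > 1
  if (any(moving)) {
    u <- (t[moving] - schedule$t_move[i[moving]]) /
      pmax(schedule$t_arrive[i[moving]] - schedule$t_move[i[moving]], 1e-9)
    gx[moving] <- schedule$x[i[moving] - 1] * (1 - u) +
      schedule$x[i[moving]] * u
    gy[moving] <- schedule$y[i[moving] - 1] * (1 - u) +
      schedule$y[i[moving]] * u
  }
  if (gaze_noise_sd > 0) {
    gx <- gx + rnorm(length(t), 0, gaze_noise_sd)
    gy <- gy + rnorm(length(t), 0, gaze_noise_sd)
  }
  synth_feature_stream(data.frame(t = t, x = gx, y = gy), model,
                       pixel_noise_sd)
}

#' Render an ocular-image sequence from a feature stream
#'
#' Renders one synthetic eye image per feature sample: the pupil stays at a
#' fixed frame position and the glint is displaced by `(U, V)` camera
#' pixels. Rows with missing `U`/`V` are rendered without a glint, so
#' downstream [extract_features()] returns `ok = FALSE` exactly there.
#'
#' @param features Data frame with columns `U`, `V`.
#' @param pupil Fixed pupil center `(x, y)` in the frame.
#' @param noise_sd,seed Pixel noise forwarded to [render_eye_image()]; each
#'   frame uses `seed + row index`.
#' @param ... Further arguments to [render_eye_image()].
#' @return List of image matrices, one per row of `features`.
#' @export
synth_image_sequence <- function(features, pupil = c(160, 120),
                                 noise_sd = 0, seed = 1, ...) {
  features <- as.data.frame(features)
  lapply(seq_len(nrow(features)), function(i) {
    glint <- if (is.na(features$U[i]) || is.na(features$V[i])) NULL else
      c(pupil[[1]] + features$U[i], pupil[[2]] + features$V[i])
    render_eye_image(pupil, glint, noise_sd = noise_sd,
                     seed = if (noise_sd > 0) seed + i else NULL, ...)
  })
}
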