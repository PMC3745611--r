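test_that("schedules balance conditions within blocks and obey the seed", {
  cfg <- sim_config("gapoverlap", trials_per_block = 20, blocks = 2,
                    seed = 3)
  sched <- make_schedule(cfg)
  expect_equal(nrow(sched), 40)
  counts <- table(sched$block, sched$gap)
  expect_true(all(counts == 4))          # each gap duration 4x per block
  expect_true(all(table(sched$block, sched$direction) == 10))
  expect_identical(make_schedule(cfg), sched)
  expect_false(identical(
    make_schedule(sim_config("gapoverlap", trials_per_block = 20,
                             blocks = 2, seed = 4)), sched))

  anti <- make_schedule(sim_config("antisaccade", trials_per_block = 20,
                                   blocks = 2, seed = 3))
  expect_true(all(table(anti$block, anti$direction) == 5))
  expect_setequal(unique(anti$condition), c("prosaccade", "antisaccade"))
  # antisaccade expected landing mirrors the target about fixation
  a <- anti[anti$condition == "antisaccade", ]
  expect_equal(a$expect_x, -a$target_x)
  expect_equal(a$expect_y, -a$target_y)
  # all fixation durations come from the 1000-1500 ms menu
  expect_true(all(anti$fix_dur %in% seq(1000, 1500, by = 100)))
})

test_that("sessions are bit-identical under a fixed seed", {
  cfg <- sim_config("antisaccade", nominal_rate = 250, trials_per_block = 8,
                    timestamp_jitter_sd = 0.3, frame_drop_prob = 0.01,
                    gap_prob = 0.002, seed = 12)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_gaze_csv(s1$recording, p1)
  write_gaze_csv(s2$recording, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(s1$truth, s2$truth)
  # emitted files pass read validation
  expect_s3_class(read_gaze_csv(p1), "gaze_recording")
})

test_that("degenerate configs yield analytic traces with exact onsets", {
  cfg <- sim_config("gapoverlap", nominal_rate = 500, trials_per_block = 10,
                    fixation_noise_sd = 0, timestamp_jitter_sd = 0,
                    frame_drop_prob = 0, landing_noise_sd = 0, seed = 2)
  ses <- simulate_session(cfg)
  tr1 <- get_trial(ses$recording, 1)$samples
  truth1 <- ses$truth[ses$truth$trial == 1, ]
  # before onset: exactly at fixation; after offset: exactly at landing
  pre <- tr1[tr1$t < truth1$t_onset, ]
  expect_true(all(pre$x == 0 & pre$y == 0))
  post <- tr1[tr1$t > truth1$t_offset, ]
  expect_equal(unique(post$x), truth1$land_x)
  expect_equal(unique(post$y), truth1$land_y)
  expect_equal(truth1$amplitude, 4.2)
  # messages describe the schedule
  msgs <- get_trial(ses$recording, 1)$messages
  expect_true(any(startsWith(msgs$text, "TARGET_ON ")))
  expect_true(any(startsWith(msgs$text, "EXPECT ")))
})

test_that("raised-cosine kinematics hit the analytic peak velocity", {
  amp <- 4.2
  D <- saccade_duration(amp)
  u <- seq(0, 1, length.out = 20001)
  v <- saccade_velocity(u, amp, D)
  expect_lt(abs(max(v) - 2 * amp / D * 1000) / (2 * amp / D * 1000), 0.01)
  # displacement integrates to the amplitude
  expect_equal(amp * saccade_progress(1), amp)
  expect_equal(amp * saccade_progress(0), 0)
  # trapezoidal integral of the velocity profile recovers the amplitude
  expect_equal(sum((v[-1] + v[-length(v)]) / 2 * diff(u) * D / 1000), amp,
               tolerance = 1e-6)
})

test_that("frame drops and tracking-loss gaps match their models", {
  cfg <- sim_config("gapoverlap", nominal_rate = 500, trials_per_block = 20,
                    blocks = 4, frame_drop_prob = 0.01, seed = 9)
  ses <- simulate_session(cfg)
  n_expected <- 80 * (3000 / 2 + 1)    # samples per trial without drops
  n_obs <- nrow(ses$recording$samples)
  dropped <- 1 - n_obs / n_expected
  se <- sqrt(0.01 * 0.99 / n_expected)
  expect_lt(abs(dropped - 0.01), 3 * se)

  cfg2 <- sim_config("gapoverlap", nominal_rate = 250, trials_per_block = 20,
                     blocks = 2, gap_prob = 0.005, gap_dur_ms = 80, seed = 10)
  ses2 <- simulate_session(cfg2)
  v <- ses2$recording$samples$valid
  expect_gt(mean(!v), 0)
  # invalid samples come in contiguous runs with mean length near
  # gap_dur_ms / delta
  r <- rle(v)
  runs <- r$lengths[!r$values]
  expect_gt(mean(runs), 0.5 * 80 / 4)
  expect_lt(mean(runs), 2.0 * 80 / 4)
  # invalid positions are NaN and ignored by construction
  expect_true(all(is.nan(ses2$recording$samples$x[!v])))
})

test_that("feature streams invert the calibration model exactly", {
  model <- calibration_model(1, 0, 0, 0, 1, 0)
  s <- data.frame(t = 1:5, x = c(0, 1, -2, 3.5, 4.2),
                  y = c(0, -1, 2, 0.5, -4))
  uv <- synth_feature_stream(s, model)
  expect_equal(uv$U, s$x)   # identity model: (U,V) = (X,Y)
  expect_equal(uv$V, s$y)

  withr::with_seed(14, {
    for (i in 1:10) {
      m <- random_calibration_model()
      uv2 <- synth_feature_stream(s, m)
      back <- predict(m, uv2)
      expect_lt(max(abs(back$x - s$x), abs(back$y - s$y)), 1e-6)
    }
  })
  singular <- calibration_model(1, 1, 0, 1, 1, 0)
  expect_error(synth_feature_stream(s, singular), "singular")
})

test_that("calibration error decreases with sample size under pixel noise", {
  sched <- calibration_schedule(grid_positions(3, 3, 9.3, 6.6))
  model <- calibration_model(0.25, 0.01, 0, -0.02, 0.3, 0)
  fit_err <- function(rate) {
    stream <- simulate_calibration_stream(model, sched, rate_hz = rate,
                                          pixel_noise_sd = 0.5)
    sel <- select_calibration_samples(stream, sched, mode = "arrival")
    fit <- fit_calibration(sel)
    sqrt(sum((fit$coefficients - model$coefficients)^2))
  }
  withr::with_seed(15, {
    e60 <- mean(replicate(10, fit_err(60)))
    e500 <- mean(replicate(10, fit_err(500)))
    expect_gt(e60, 0)
    expect_lt(e500, e60)
  })
})

test_that("rendered image sequences close the loop on (U, V)", {
  u_sweep <- seq(-20, 20, length.out = 9)
  feats <- data.frame(U = u_sweep, V = rep(3, 9))
  imgs <- synth_image_sequence(feats, pupil = c(160, 120))
  rec <- dplyr::bind_rows(lapply(imgs, extract_features))
  expect_true(all(rec$ok))
  expect_lt(max(abs(rec$U - u_sweep)), 0.5)
  expect_lt(max(abs(rec$V - 3)), 0.5)
  expect_false(is.unsorted(rec$U))   # monotone sweep recovered monotone
  # frames without a glint yield ok = FALSE exactly there
  feats$U[4:5] <- NA
  imgs2 <- synth_image_sequence(feats, pupil = c(160, 120))
  rec2 <- dplyr::bind_rows(lapply(imgs2, extract_features))
  expect_identical(rec2$ok, !is.na(feats$U))
  # constant features render identical frames when noise is off
  same <- synth_image_sequence(data.frame(U = c(5, 5), V = c(2, 2)))
  expect_identical(same[[1]], same[[2]])
})
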