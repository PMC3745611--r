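test_that("a stationary trace yields one full-span fixation", {
  tr <- data.frame(t = seq(0, 1000, by = 4), x = 2, y = -1, valid = TRUE)
  ev <- detect_events(tr, detection_params(), filter = NULL)
  expect_equal(sum(ev$event == "saccade"), 0)
  fix <- ev[ev$event == "fixation", ]
  expect_equal(nrow(fix), 1)
  expect_equal(c(fix$onset, fix$offset), c(0, 1000))
  expect_equal(c(fix$cx, fix$cy), c(2, -1))
})

test_that("duration gating and burst merging follow the algorithm", {
  # two 16-ms supra bursts separated by an 8-ms sub-threshold gap:
  # 8 < min_fixation_ms merges them into a single saccade
  delta <- 4
  pattern <- c(rep(0, 10), rep(1, 5), 0, rep(1, 5), rep(0, 10))
  pt <- pattern_trial(pattern, delta)
  ev <- detect_events(pt$samples, detection_params(22, 12, 12),
                      filter = NULL, speed = pt$speed)
  sac <- ev[ev$event == "saccade", ]
  expect_equal(nrow(sac), 1)
  expect_equal(sac$onset, 10 * delta)   # first supra sample of burst 1
  expect_equal(sac$offset, 20 * delta)  # last supra sample of burst 2

  # a lone burst spanning 6 ms is below the duration gate
  short <- pattern_trial(c(rep(0, 10), 1, 1, 1, rep(0, 10)), delta_ms = 3)
  ev2 <- detect_events(short$samples, detection_params(22, 12, 12),
                       filter = NULL, speed = short$speed)
  expect_equal(sum(ev2$event == "saccade"), 0)

  # with a 20-ms gap (>= min_fixation) the bursts stay separate
  pattern3 <- c(rep(0, 10), rep(1, 5), rep(0, 5), rep(1, 5), rep(0, 10))
  pt3 <- pattern_trial(pattern3, delta)
  ev3 <- detect_events(pt3$samples, detection_params(22, 12, 12),
                       filter = NULL, speed = pt3$speed)
  expect_equal(sum(ev3$event == "saccade"), 2)
})

test_that("merge_candidates merges short gaps in one idempotent pass", {
  # gaps of 8, 20, 5 ms with threshold 12: first and third merge
  cand <- data.frame(onset = c(0, 24, 60, 81), offset = c(16, 40, 76, 97))
  m <- merge_candidates(cand, 12)
  expect_equal(m$onset, c(0, 60))
  expect_equal(m$offset, c(40, 97))
  # idempotent, and all surviving gaps >= threshold
  expect_identical(merge_candidates(m, 12), m)
  expect_true(all(m$onset[-1] - m$offset[-nrow(m)] >= 12))
  # empty input and all-large-gap input are fixed points
  empty <- data.frame(onset = numeric(0), offset = numeric(0))
  expect_equal(nrow(merge_candidates(empty, 12)), 0)
  spaced <- data.frame(onset = c(0, 50), offset = c(10, 60))
  expect_equal(as.data.frame(merge_candidates(spaced, 12)), spaced)
  expect_error(merge_candidates(data.frame(onset = c(50, 0),
                                           offset = c(60, 10)), 12),
               "sorted")
})

test_that("detector agrees with the literal reference on random patterns", {
  withr::with_seed(31, {
    params <- detection_params(22, 12, 12)
    for (rep in 1:400) {
      len <- sample(3:20, 1)
      pattern <- runif(len) < 0.5
      pt <- pattern_trial(pattern, delta_ms = 4)
      ev <- detect_events(pt$samples, params, filter = NULL,
                          speed = pt$speed)
      ref <- oracle_detect(pt$samples$t, pt$speed, 22, 12, 12)
      sac <- ev[ev$event == "saccade", ]
      fix <- ev[ev$event == "fixation", ]
      expect_equal(sac$onset, ref$saccades$onset)
      expect_equal(sac$offset, ref$saccades$offset)
      expect_equal(fix$onset, ref$fixations$onset)
      expect_equal(fix$offset, ref$fixations$offset)
    }
  })
})

test_that("saccades and fixations tile the span; gaps are flagged", {
  withr::with_seed(32, {
    for (rep in 1:20) {
      pattern <- runif(60) < 0.4
      pt <- pattern_trial(pattern, delta_ms = 4)
      ev <- detect_events(pt$samples, detection_params(22, 12, 12),
                          filter = NULL, speed = pt$speed)
      ev <- ev[order(ev$onset), ]
      # tiling: consecutive events abut exactly, covering the whole span
      expect_equal(ev$onset[1], pt$samples$t[1])
      expect_equal(ev$offset[nrow(ev)], max(pt$samples$t))
      if (nrow(ev) > 1) {
        expect_equal(ev$onset[-1], ev$offset[-nrow(ev)])
      }
    }
  })
  # events overlapping invalid samples carry the unreliable flag
  tr <- data.frame(t = seq(0, 400, by = 4), x = 0, y = 0, valid = TRUE)
  speed <- rep(5, nrow(tr))
  speed[40:50] <- 40
  tr$valid[44:46] <- FALSE
  ev <- detect_events(tr, detection_params(22, 12, 12), filter = NULL,
                      speed = speed)
  sac <- ev[ev$event == "saccade", ]
  expect_equal(nrow(sac), 1)
  expect_true(sac$unreliable)
  expect_true(any(ev$unreliable[ev$event == "fixation"]) == FALSE)
})

test_that("raising the velocity threshold never adds saccade time", {
  withr::with_seed(33, {
    for (rep in 1:15) {
      n <- 300
      tr <- data.frame(t = seq_len(n) * 4, x = cumsum(rnorm(n, 0, 0.2)),
                       y = cumsum(rnorm(n, 0, 0.2)), valid = TRUE)
      total <- vapply(c(10, 22, 40, 80), function(vt) {
        ev <- detect_events(tr, detection_params(vt, 12, 12), filter = NULL)
        sum(ev$duration[ev$event == "saccade"])
      }, numeric(1))
      expect_true(all(diff(total) <= 1e-9))
    }
  })
})

test_that("a simulated 4.2 deg saccade is detected accurately at 500 Hz", {
  cfg <- sim_config("gapoverlap", nominal_rate = 500, trials_per_block = 10,
                    fixation_noise_sd = 0.1, landing_noise_sd = 0,
                    seed = 77)
  ses <- simulate_session(cfg)
  ev <- detect_session(ses$recording, detection_params(22, 12, 12),
                       filter = filter_spec(60))
  m <- match_detections(ses$truth, ev, max_onset_err = 12 + 2)
  expect_true(all(m$detected))
  expect_lt(max(abs(m$amp_err)), 0.3)
})

test_that("detection refuses traces with fewer than 3 valid samples", {
  tr <- data.frame(t = c(0, 4, 8), x = 0, y = 0,
                   valid = c(TRUE, TRUE, FALSE))
  expect_error(detect_events(tr), "3 valid")
})
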