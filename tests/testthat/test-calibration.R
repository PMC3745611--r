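test_that("sample selection windows follow the stated boundary rules", {
  sched <- calibration_schedule(grid_positions(3, 3, 9.3, 6.6)[1:3, ],
                                dwell_ms = 1000, move_ms = 0)
  # crafted stream with samples exactly on window edges
  t <- c(100, 200, 201, 500, 799, 800, 900, 1100, 1201, 1500)
  stream <- data.frame(t = t, U = t, V = -t)
  kept <- select_calibration_samples(stream, sched, mode = "exclusion")
  # kept region per dwell is the open interval (arrive+200, arrive+800)
  expect_setequal(kept$t, c(201, 500, 799, 1201, 1500))
  kept2 <- select_calibration_samples(stream, sched, mode = "arrival")
  expect_identical(kept, kept2)  # jump schedules: modes coincide

  # samples are labelled with the dwelt target
  expect_equal(kept$target_x[kept$t == 1201],
               sched$x[2])
  expect_error(
    select_calibration_samples(data.frame(t = 50, U = 0, V = 0), sched),
    "insufficient calibration data")
})

test_that("noiseless fits recover any nonsingular model to 1e-9", {
  uv <- tidyr::expand_grid(U = c(-20, 0, 20), V = c(-15, 0, 15))
  withr::with_seed(42, {
    for (i in 1:25) {
      model <- random_calibration_model()
      target <- predict(model, uv)
      fit <- fit_calibration(
        data.frame(uv, target_x = target$x, target_y = target$y))
      rel <- abs(fit$coefficients - model$coefficients) /
        pmax(abs(model$coefficients), 1e-8)
      expect_lt(max(rel), 1e-9)
    }
  })
  # identity mapping
  idf <- fit_calibration(data.frame(U = c(0, 1, 0, 2), V = c(0, 0, 1, 2),
                                    target_x = c(0, 1, 0, 2),
                                    target_y = c(0, 0, 1, 2)))
  expect_equal(unname(idf$coefficients), c(1, 0, 0, 0, 1, 0),
               tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  collinear <- data.frame(U = 1:5, V = 2 * (1:5), target_x = 1:5,
                          target_y = 1:5)
  expect_error(fit_calibration(collinear), "rank-deficient")
  expect_error(fit_calibration(collinear[1:2, ]), "at least 3")
})

test_that("prediction is the exact affine map", {
  m <- calibration_model(0.2, 0.01, -1.5, -0.02, 0.25, 2)
  p <- predict(m, data.frame(U = 0, V = 0))
  expect_equal(c(p$x, p$y), c(-1.5, 2))  # intercepts
  idm <- calibration_model(1, 0, 0, 0, 1, 0)
  p2 <- predict(idm, data.frame(U = 3.2, V = -1.5))
  expect_equal(c(p2$x, p2$y), c(3.2, -1.5))
  # midpoint preservation (affinity)
  a <- predict(m, data.frame(U = 4, V = -7))
  b <- predict(m, data.frame(U = -10, V = 3))
  mid <- predict(m, data.frame(U = -3, V = -2))
  expect_equal(mid$x, (a$x + b$x) / 2, tolerance = 1e-12)
  expect_equal(mid$y, (a$y + b$y) / 2, tolerance = 1e-12)
})

test_that("fit report is internally consistent and residuals orthogonal", {
  withr::with_seed(8, {
    uv <- data.frame(U = rnorm(60, 0, 10), V = rnorm(60, 0, 8))
    model <- random_calibration_model()
    tgt <- predict(model, uv)
    samples <- data.frame(uv, target_x = tgt$x + rnorm(60, 0, 0.3),
                          target_y = tgt$y + rnorm(60, 0, 0.3))
    fit <- fit_calibration(samples)
    pred <- predict(fit, samples)
    sse <- sum((pred$x - samples$target_x)^2 +
                 (pred$y - samples$target_y)^2)
    expect_equal(sse, fit$sse, tolerance = 1e-10)
    # normal equations: residuals orthogonal to 1, U, V
    rx <- samples$target_x - pred$x
    ry <- samples$target_y - pred$y
    for (v in list(rep(1, 60), samples$U, samples$V)) {
      expect_lt(abs(sum(rx * v)), 1e-8)
      expect_lt(abs(sum(ry * v)), 1e-8)
    }
    expect_named(glance(fit), c("n", "sse", "mean_error", "n_targets"))
    expect_equal(nrow(tidy(fit)), 6)
  })
})

test_that("calibration error metric is the mean Euclidean distance", {
  m <- calibration_model(1, 0, 0, 0, 1, 0)
  perfect <- data.frame(U = c(-5, 0, 5), V = c(0, 1, -1),
                        target_x = c(-5, 0, 5), target_y = c(0, 1, -1))
  expect_equal(calibration_error(m, perfect)$overall, 0)
  # single sample off by (0.3, 0.4): 3-4-5 triangle
  off <- data.frame(U = 0.3, V = 0.4, target_x = 0, target_y = 0)
  expect_equal(calibration_error(m, off)$overall, 0.5)
})

test_that("coefficient error shrinks with more noisy samples per point", {
  sched9 <- calibration_schedule(grid_positions(3, 3, 9.3, 6.6),
                                 dwell_ms = 1000)
  model <- calibration_model(0.25, 0.02, 0.5, -0.01, 0.22, -0.3)
  coef_err <- function(rate) {
    stream <- simulate_calibration_stream(model, sched9, rate_hz = rate,
                                          pixel_noise_sd = 0.5)
    sel <- select_calibration_samples(stream, sched9, mode = "arrival")
    fit <- fit_calibration(sel)
    sqrt(sum((fit$coefficients - model$coefficients)^2))
  }
  withr::with_seed(13, {
    # 16x the samples should give roughly 4x smaller error; allow slack
    e_small <- mean(replicate(8, coef_err(30)))
    e_large <- mean(replicate(8, coef_err(480)))
    expect_lt(e_large, e_small / 2)
  })
})

test_that("accept/reject against an accuracy criterion is monotone in noise", {
  sched9 <- calibration_schedule(grid_positions(3, 3, 9.3, 6.6),
                                 dwell_ms = 1000)
  model <- calibration_model(0.3, 0, 0, 0, 0.3, 0)
  err_at <- function(sd) {
    stream <- simulate_calibration_stream(model, sched9, rate_hz = 120,
                                          gaze_noise_sd = sd)
    sel <- select_calibration_samples(stream, sched9, mode = "arrival")
    calibration_error(fit_calibration(sel), sel)$overall
  }
  withr::with_seed(21, {
    errs <- vapply(c(0.1, 0.5, 1.5), err_at, numeric(1))
    expect_true(all(diff(errs) > 0))
    expect_lt(errs[1], 0.8)   # clean sessions pass the 0.8 deg criterion
    expect_gt(errs[3], 0.8)   # very noisy sessions fail it
  })
})

test_that("calibration CSV round trip preserves samples", {
  withr::with_seed(5, {
    s <- tibble::tibble(t = sort(runif(20, 0, 9000)), U = rnorm(20),
                        V = rnorm(20), target_x = rnorm(20),
                        target_y = rnorm(20))
  })
  path <- withr::local_tempfile(fileext = ".csv")
  write_calibration_csv(s, path)
  expect_identical(read_calibration_csv(path), s)
  writeLines(c("C,1,2,3,4,5", "X,no"), path)
  expect_error(read_calibration_csv(path), "line 2")
})
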