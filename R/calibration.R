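#' Build a calibration schedule
#'
#' Timeline of the calibration target: an ordered list of positions, each
#' preceded by a travel period of `move_ms` (0 for jumps) and held for
#' `dwell_ms`. The first move starts at t = 0, so the target arrives at
#' position k at `t = k * move_ms + (k - 1) * dwell_ms`. At least 3
#' non-collinear positions are required for an identifiable fit.
#'
#' @param positions Data frame with columns `x`, `y` (degrees), one row per
#'   target location in visiting order. The classic arrangement is a 3 x 3
#'   grid; see [grid_positions()].
#' @param dwell_ms Per-position fixation duration, ms (default 1000).
#' @param move_ms Target travel time between positions, ms (0 = jumps).
#' @return A `calibration_schedule` tibble with columns `x`, `y`,
#'   `t_move` (travel start), `t_arrive` (arrival), `t_depart` (end of
#'   dwell), and attributes `dwell_ms`, `move_ms`.
#' @export
calibration_schedule <- function(positions, dwell_ms = 1000, move_ms = 0) {
  positions <- as.data.frame(positions)
  stopifnot(all(c("x", "y") %in% names(positions)), dwell_ms > 0,
            move_ms >= 0)
  n <- nrow(positions)
  if (n < 3) abort("at least 3 calibration positions are required")
  k <- seq_len(n)
  out <- tibble::tibble(
    x = positions$x, y = positions$y,
    t_move = (k - 1) * (dwell_ms + move_ms),
    t_arrive = (k - 1) * (dwell_ms + move_ms) + move_ms,
    t_depart = k * dwell_ms + (k - 1) * move_ms + move_ms
  )
  attr(out, "dwell_ms") <- dwell_ms
  attr(out, "move_ms") <- move_ms
  class(out) <- c("calibration_schedule", class(out))
  out
}

#' Grid of target positions
#'
#' Node positions of an invisible rectangular grid centered on the screen
#' center, listed row by row. The 3 x 3 calibration grid uses spacings of
#' 9.3 deg (horizontal) by 6.6 deg (vertical); the 6 x 6 accuracy-test grid
#' uses 2.7 deg in both directions.
#'
#' @param nx,ny Number of columns and rows.
#' @param dx,dy Spacing between adjacent nodes, degrees.
#' @return Tibble with columns `x`, `y`.
#' @export
grid_positions <- function(nx = 3, ny = 3, dx = 9.3, dy = 6.6) {
  gx <- (seq_len(nx) - (nx + 1) / 2) * dx
  gy <- (seq_len(ny) - (ny + 1) / 2) * dy
  tidyr::expand_grid(y = gy, x = gx)[, c("x", "y")]
}

#' Select calibration samples by temporal window
#'
#' Two selection rules are supported, matching the two conventions used
#' with moving calibration targets. `"exclusion"` discards samples recorded
#' within `exclude_ms` before and after any target movement (the movement
#' interval itself included); `"arrival"` keeps only samples recorded
#' between `window[1]` and `window[2]` ms after the target arrived at a new
#' position. Boundary comparisons are strict: a sample exactly on a window
#' edge is excluded, so the kept region is an open interval. For jump
#' schedules with dwell `window[2] + exclude_ms` the two modes select
#' identical samples. Each kept sample is labelled with the position the
#' target occupied at its timestamp.
#'
#' @param samples Data frame with columns `t`, `U`, `V` (feature-space
#'   calibration stream).
#' @param schedule A [calibration_schedule()].
#' @param mode `"exclusion"` or `"arrival"`.
#' @param exclude_ms Half-width of the exclusion window around target moves
#'   (exclusion mode), ms.
#' @param window Length-2 numeric, ms after arrival (arrival mode).
#' @return A tibble with columns `t`, `U`, `V`, `target_x`, `target_y`.
#' @export
select_calibration_samples <- function(samples, schedule,
                                       mode = c("exclusion", "arrival"),
                                       exclude_ms = 200,
                                       window = c(200, 800)) {
  mode <- match.arg(mode)
  samples <- tibble::as_tibble(as.data.frame(samples))
  stopifnot(all(c("t", "U", "V") %in% names(samples)),
            inherits(schedule, "calibration_schedule"))
  t <- samples$t
  if (mode == "exclusion") {
    # target transitions: every move, plus the target offset ending the
    # calibration (treated as a transition as well)
    mv_start <- c(schedule$t_move, max(schedule$t_depart))
    mv_end <- c(schedule$t_arrive, max(schedule$t_depart))
    excluded <- rep(FALSE, length(t))
    for (i in seq_along(mv_start)) {
      excluded <- excluded |
        (t >= mv_start[i] - exclude_ms & t <= mv_end[i] + exclude_ms)
    }
    keep <- !excluded & t < max(schedule$t_depart)
  } else {
    keep <- rep(FALSE, length(t))
    for (i in seq_len(nrow(schedule))) {
      keep <- keep |
        (t > schedule$t_arrive[i] + window[1] &
           t < schedule$t_arrive[i] + window[2])
    }
  }
  # label with the position dwelt at the sample's timestamp
  pos <- findInterval(t, schedule$t_arrive)
  pos[pos < 1] <- NA_integer_
  keep <- keep & !is.na(pos)
  if (!any(keep)) abort("insufficient calibration data: empty selection")
  tibble::tibble(t = t[keep], U = samples$U[keep], V = samples$V[keep],
                 target_x = schedule$x[pos[keep]],
                 target_y = schedule$y[pos[keep]])
}

#' Fit the linear gaze calibration model
#'
#' Estimates the six coefficients of the linear mapping from the
#' pupil-to-Purkinje feature vector to screen gaze,
#' `X = aX*U + bX*V + cX` and `Y = aY*U + bY*V + cY`, by least squares.
#' Minimising the sum of squared distances between predicted gaze and
#' target separates into two independent ordinary linear regressions, which
#' are solved exactly in closed form (via `lm`). The fit is identifiable
#' when at least 3 samples with non-collinear `(U, V)` are present.
#'
#' @param samples Data frame with columns `U`, `V`, `target_x`, `target_y`
#'   (e.g. from [select_calibration_samples()]).
#' @return An object of class `gaze_calibration`: coefficients, the fitted
#'   sum of squared distances (`sse`, deg^2), and a per-target error table.
#'   Supports [predict()], [tidy()], [glance()] and [autoplot()].
#' @examples
#' s <- data.frame(U = c(0, 1, 0, 1), V = c(0, 0, 1, 1),
#'                 target_x = c(0, 1, 0, 1), target_y = c(0, 0, 1, 1))
#' fit <- fit_calibration(s)
#' predict(fit, data.frame(U = 3.2, V = -1.5))
#' @export
fit_calibration <- function(samples) {
  samples <- as.data.frame(samples)
  stopifnot(all(c("U", "V", "target_x", "target_y") %in% names(samples)))
  if (nrow(samples) < 3) abort("at least 3 calibration samples are required")
  X <- cbind(1, samples$U, samples$V)
  if (qr(X)$rank < 3) {
    abort("rank-deficient calibration design: (U, V) samples are collinear")
  }
  fit <- lm(cbind(target_x, target_y) ~ U + V, data = samples)
  cf <- coef(fit)  # rows: (Intercept), U, V; cols: target_x, target_y
  coefs <- c(a_X = cf["U", "target_x"], b_X = cf["V", "target_x"],
             c_X = cf["(Intercept)", "target_x"],
             a_Y = cf["U", "target_y"], b_Y = cf["V", "target_y"],
             c_Y = cf["(Intercept)", "target_y"])
  res <- stats::residuals(fit)
  obj <- structure(
    list(coefficients = coefs, sse = sum(res^2), n = nrow(samples)),
    class = "gaze_calibration")
  obj$per_target <- calibration_error(obj, samples)$per_target
  obj
}

#' Apply a calibration model to feature-space samples
#'
#' Computes exactly `(aX*U + bX*V + cX, aY*U + bY*V + cY)`. The mapping is
#' affine, so midpoints are preserved exactly.
#'
#' @param object A `gaze_calibration`.
#' @param newdata Data frame with columns `U`, `V`.
#' @param ... Unused.
#' @return Tibble with gaze columns `x`, `y` (degrees).
#' @export
predict.gaze_calibration <- function(object, newdata, ...) {
  cf <- unname(object$coefficients[c("a_X", "b_X", "c_X",
                                     "a_Y", "b_Y", "c_Y")])
  tibble::tibble(
    x = cf[1] * newdata$U + cf[2] * newdata$V + cf[3],
    y = cf[4] * newdata$U + cf[5] * newdata$V + cf[6]
  )
}

#' Calibration accuracy against fixation targets
#'
#' Mean Euclidean distance (degrees) between predicted gaze and the target
#' position, per target location and averaged over locations. The average
#' over the nine locations of a 3 x 3 grid is the usual accept/recalibrate
#' criterion (e.g. accept below 0.8 deg).
#'
#' @param model A `gaze_calibration`.
#' @param samples Data frame with columns `U`, `V`, `target_x`, `target_y`.
#' @return List with `per_target` (tibble: `target_x`, `target_y`, `n`,
#'   `mean_error`) and `overall` (mean of per-target means, deg).
#' @export
calibration_error <- function(model, samples) {
  stopifnot(inherits(model, "gaze_calibration"))
  samples <- as.data.frame(samples)
  pred <- predict(model, samples)
  err <- sqrt((pred$x - samples$target_x)^2 + (pred$y - samples$target_y)^2)
  per <- tibble::tibble(target_x = samples$target_x,
                        target_y = samples$target_y, error = err) |>
    dplyr::group_by(.data$target_x, .data$target_y) |>
    dplyr::summarise(n = dplyr::n(), mean_error = mean(.data$error),
                     .groups = "drop")
  list(per_target = per, overall = mean(per$mean_error))
}

#' @export
print.gaze_calibration <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(
    "<gaze_calibration> X = %+.4g U %+.4g V %+.4g | Y = %+.4g U %+.4g V %+.4g\n",
    cf["a_X"], cf["b_X"], cf["c_X"], cf["a_Y"], cf["b_Y"], cf["c_Y"]))
  cat(sprintf("  fitted on %d samples, SSE %.4g deg^2, mean per-target error %.3g deg\n",
              x$n, x$sse, mean(x$per_target$mean_error)))
  invisible(x)
}

#' @describeIn fit_calibration Coefficients as a one-row-per-term tibble.
#' @param x A `gaze_calibration`.
#' @param ... Unused.
#' @export
tidy.gaze_calibration <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @describeIn fit_calibration One-row fit summary (n, SSE, mean error).
#' @export
glance.gaze_calibration <- function(x, ...) {
  tibble::tibble(n = x$n, sse = x$sse,
                 mean_error = mean(x$per_target$mean_error),
                 n_targets = nrow(x$per_target))
}
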