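# Ocular images are numeric matrices (rows x cols) with 8-bit intensities
# in [0, 255]. Point coordinates are (x, y) with x along columns and y along
# rows, origin at the top-left pixel whose center is (1, 1); sub-pixel
# positions refer to pixel centers.

#' Detection configuration for ocular images
#'
#' Thresholds and gates for pupil/Purkinje detection. The pupil is the
#' large dark blob (intensity below `dark_threshold`, area within
#' `pupil_area_range`); the Purkinje image is the small bright corneal
#' glint (intensity above `bright_threshold`) searched within
#' `glint_roi_radius` pixels of the detected pupil center, mirroring the
#' physical configuration (the glint sits on the cornea over the pupil).
#'
#' @param dark_threshold Intensity below which pixels count as pupil.
#' @param bright_threshold Intensity above which pixels count as glint.
#' @param pupil_area_range Length-2 vector, admissible pupil area in px.
#' @param glint_roi_radius Search radius around the pupil center, px.
#' @return An object of class `eye_config`.
#' @export
eye_config <- function(dark_threshold = 80, bright_threshold = 150,
                       pupil_area_range = c(200, 20000),
                       glint_roi_radius = 40) {
  structure(list(dark_threshold = dark_threshold,
                 bright_threshold = bright_threshold,
                 pupil_area_range = pupil_area_range,
                 glint_roi_radius = glint_roi_radius),
            class = "eye_config")
}

# intensity-weighted centroid of a labelled component
weighted_centroid <- function(weight, rows, cols) {
  w <- sum(weight)
  c(x = sum(weight * cols) / w, y = sum(weight * rows) / w)
}

#' Detect the pupil center in an ocular image
#'
#' Thresholds the image at `dark_threshold`, labels connected dark
#' components, keeps those whose area lies within `area_range`, and returns
#' the intensity-weighted sub-pixel centroid of the largest (weights
#' `dark_threshold - intensity`, so deeper-dark pixels count more and the
#' anti-aliased rim contributes fractionally).
#'
#' @param img Numeric matrix, 8-bit grayscale ocular image.
#' @param dark_threshold Intensity threshold (strictly below = dark).
#' @param area_range Length-2 vector of admissible component areas, px.
#' @return List with `ok` (logical), `center` (named vector `x`, `y` or
#'   `NULL`) and `area`.
#' @export
detect_pupil <- function(img, dark_threshold = 80,
                         area_range = c(200, 20000)) {
  mask <- img < dark_threshold
  if (!any(mask)) return(list(ok = FALSE, center = NULL, area = 0L))
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  eligible <- which(areas >= area_range[1] & areas <= area_range[2])
  if (length(eligible) == 0) return(list(ok = FALSE, center = NULL, area = 0L))
  best <- eligible[which.max(areas[eligible])]
  idx <- which(lab == best, arr.ind = TRUE)
  w <- dark_threshold - img[idx]
  cen <- weighted_centroid(w, idx[, 1], idx[, 2])
  list(ok = TRUE, center = c(x = unname(cen["x"]), y = unname(cen["y"])),
       area = areas[best])
}

#' Detect the Purkinje (corneal-reflection) center
#'
#' Within a circular region of interest, thresholds at `bright_threshold`,
#' labels connected bright components, and returns the intensity-weighted
#' centroid of the brightest one (largest peak intensity; weights
#' `intensity - bright_threshold`).
#'
#' @param img Numeric matrix, 8-bit grayscale ocular image.
#' @param bright_threshold Intensity threshold (strictly above = bright).
#' @param roi_center Named or plain numeric `(x, y)`, typically the
#'   detected pupil center.
#' @param roi_radius Search radius, px.
#' @return List with `ok` and `center` as in [detect_pupil()].
#' @export
detect_purkinje <- function(img, bright_threshold = 150, roi_center,
                            roi_radius = 40) {
  nr <- nrow(img); nc <- ncol(img)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  rows <- matrix(seq_len(nr), nr, nc)
  roi <- (cols - roi_center[[1]])^2 + (rows - roi_center[[2]])^2 <=
    roi_radius^2
  mask <- roi & img > bright_threshold
  if (!any(mask)) return(list(ok = FALSE, center = NULL))
  lab <- EBImage::bwlabel(mask)
  peaks <- vapply(seq_len(max(lab)), function(k) {
    if (any(lab == k)) max(img[lab == k]) else -Inf
  }, numeric(1))
  best <- which.max(peaks)
  idx <- which(lab == best, arr.ind = TRUE)
  w <- img[idx] - bright_threshold
  cen <- weighted_centroid(w, idx[, 1], idx[, 2])
  list(ok = TRUE, center = c(x = unname(cen["x"]), y = unname(cen["y"])))
}

#' Extract the pupil-to-Purkinje feature vector from an ocular image
#'
#' Runs [detect_pupil()] then [detect_purkinje()] (with the region of
#' interest centered on the pupil) and forms the feature vector
#' `(U, V) = purkinje_center - pupil_center` in camera pixels. This vector
#' is approximately invariant to head translation and varies with eye
#' rotation, which is what makes it the regressor of the gaze calibration
#' model. Failure of either detector is encoded as `ok = FALSE`.
#'
#' @param img Numeric matrix, 8-bit grayscale ocular image.
#' @param cfg An [eye_config()].
#' @return One-row tibble: `pupil_x`, `pupil_y`, `purkinje_x`,
#'   `purkinje_y`, `U`, `V`, `ok`.
#' @export
extract_features <- function(img, cfg = eye_config()) {
  stopifnot(inherits(cfg, "eye_config"))
  na_row <- tibble::tibble(pupil_x = NA_real_, pupil_y = NA_real_,
                           purkinje_x = NA_real_, purkinje_y = NA_real_,
                           U = NA_real_, V = NA_real_, ok = FALSE)
  pup <- detect_pupil(img, cfg$dark_threshold, cfg$pupil_area_range)
  if (!pup$ok) return(na_row)
  glint <- detect_purkinje(img, cfg$bright_threshold, pup$center,
                           cfg$glint_roi_radius)
  if (!glint$ok) {
    na_row$pupil_x <- pup$center[["x"]]
    na_row$pupil_y <- pup$center[["y"]]
    return(na_row)
  }
  tibble::tibble(
    pupil_x = pup$center[["x"]], pupil_y = pup$center[["y"]],
    purkinje_x = glint$center[["x"]], purkinje_y = glint$center[["y"]],
    U = glint$center[["x"]] - pup$center[["x"]],
    V = glint$center[["y"]] - pup$center[["y"]], ok = TRUE)
}

#' Render a synthetic ocular image
#'
#' Draws a uniform iris background, a darker pupil disk with an
#' anti-aliased (coverage-shaded) rim, and a bright Gaussian glint, then
#' optionally adds seeded Gaussian pixel noise. Intensities are rounded to
#' integer 8-bit levels and clamped to [0, 255]. With `noise_sd = 0` the
#' image is fully deterministic.
#'
#' @param pupil Numeric `(x, y)`, pupil disk center (must lie in frame).
#' @param glint Numeric `(x, y)` or `NULL` to disable the glint.
#' @param width,height Image size in px (camera frames are 320 x 240).
#' @param pupil_radius Pupil disk radius, px.
#' @param bg,pupil_value Iris background and pupil interior intensities.
#' @param glint_amp,glint_sd Peak amplitude (added to the underlying
#'   intensity) and Gaussian radius of the glint.
#' @param noise_sd Additive Gaussian pixel noise SD (intensity levels).
#' @param seed Integer seed for the noise (required when `noise_sd > 0`).
#' @return Numeric matrix `height` x `width`.
#' @export
render_eye_image <- function(pupil, glint = NULL, width = 320, height = 240,
                             pupil_radius = 30, bg = 120, pupil_value = 20,
                             glint_amp = 220, glint_sd = 1.5, noise_sd = 0,
                             seed = NULL) {
  in_frame <- function(p) {
    p[[1]] >= 1 && p[[1]] <= width && p[[2]] >= 1 && p[[2]] <= height
  }
  if (!in_frame(pupil)) abort("pupil center out of frame")
  if (!is.null(glint) && !in_frame(glint)) abort("glint center out of frame")
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  rows <- matrix(seq_len(height), height, width)
  d_pup <- sqrt((cols - pupil[[1]])^2 + (rows - pupil[[2]])^2)
  coverage <- pmin(pmax(pupil_radius + 0.5 - d_pup, 0), 1)
  img <- bg - (bg - pupil_value) * coverage
  if (!is.null(glint)) {
    d2 <- (cols - glint[[1]])^2 + (rows - glint[[2]])^2
    img <- img + glint_amp * exp(-d2 / (2 * glint_sd^2))
  }
  if (noise_sd > 0) {
    if (is.null(seed)) abort("a seed is required when noise_sd > 0")
    noise <- withr::with_seed(seed,
      matrix(rnorm(height * width, 0, noise_sd), height, width))
    img <- img + noise
  }
  pmin(pmax(round(img), 0), 255)
}

#' Read/write 8-bit grayscale PNG ocular images
#'
#' Thin wrappers over the png package mapping between gazekit's numeric
#' 0-255 matrices and PNG's 0-1 grayscale.
#'
#' @param path File path.
#' @return `read_eye_png` returns a numeric matrix in [0, 255].
#' @export
read_eye_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  round(m * 255)
}

#' @rdname read_eye_png
#' @param img Numeric matrix in [0, 255].
#' @export
write_eye_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 255) / 255, path)
  invisible(img)
}
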