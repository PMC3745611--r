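# CSV dialect, one record per line:
#   #META,key,value            (nominal_rate, viewing_distance_cm,
#                               pixels_per_cm, resolution as WxH)
#   #TRIAL_START,<index> / #TRIAL_END,<index>
#   S,<t_ms>,<x_deg>,<y_deg>,<valid 0|1>
#   M,<t_ms>,<text>            (commas in text escaped as \,)
# Floats are written with "%.17g" so finite values round-trip bit-exactly.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "nan"
  out
}

parse_num <- function(x) suppressWarnings(as.numeric(x))

escape_msg <- function(text) gsub(",", "\\\\,", text, fixed = FALSE)

unescape_msg <- function(text) gsub("\\\\,", ",", text)

# split on commas not preceded by a backslash
split_dialect <- function(line) strsplit(line, "(?<!\\\\),", perl = TRUE)[[1]]

#' Write a gaze recording to a CSV file
#'
#' Serialises a [gaze_recording()] in gazekit's line-oriented CSV dialect:
#' `#META` header records, `#TRIAL_START`/`#TRIAL_END` trial boundaries,
#' `S,t,x,y,valid` sample rows and `M,t,text` message rows (commas in
#' message text are escaped as `\,`). Within each trial, samples and
#' messages are interleaved in timestamp order. Finite numbers round-trip
#' bit-exactly through [read_gaze_csv()].
#'
#' @param rec A `gaze_recording`.
#' @param path Output file path.
#' @return `rec`, invisibly.
#' @export
write_gaze_csv <- function(rec, path) {
  stopifnot(inherits(rec, "gaze_recording"))
  lines <- c(
    sprintf("#META,nominal_rate,%s", fmt_num(rec$nominal_rate))
  )
  if (!is.null(rec$geometry)) {
    g <- rec$geometry
    lines <- c(lines,
      sprintf("#META,viewing_distance_cm,%s", fmt_num(g$viewing_distance_cm)),
      sprintf("#META,pixels_per_cm,%s", fmt_num(g$pixels_per_cm)),
      sprintf("#META,resolution,%gx%g", g$resolution[1], g$resolution[2]))
  }
  for (idx in trial_indices(rec)) {
    tr <- get_trial(rec, idx)
    srow <- if (nrow(tr$samples)) {
      sprintf("S,%s,%s,%s,%d", fmt_num(tr$samples$t), fmt_num(tr$samples$x),
              fmt_num(tr$samples$y), as.integer(tr$samples$valid))
    } else character()
    mrow <- if (nrow(tr$messages)) {
      sprintf("M,%s,%s", fmt_num(tr$messages$t), escape_msg(tr$messages$text))
    } else character()
    tall <- c(tr$samples$t, tr$messages$t)
    body <- c(srow, mrow)[order(tall, method = "radix")]
    lines <- c(lines, sprintf("#TRIAL_START,%d", idx), body,
               sprintf("#TRIAL_END,%d", idx))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(rec)
}

#' Read a gaze recording from a CSV file
#'
#' Parses the dialect written by [write_gaze_csv()] and reconstructs the
#' recording, including trial boundaries. Malformed rows raise a parse
#' error naming the offending line; nonmonotonic sample timestamps within a
#' trial raise a validation error.
#'
#' @param path Input file path.
#' @return A [gaze_recording()].
#' @export
read_gaze_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  cur_trial <- NA_integer_
  st <- sm <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line)) next
    f <- split_dialect(line)
    bad <- function(why) {
      abort(sprintf("parse error at line %d: %s (%s)", i, why, line))
    }
    switch(f[[1]],
      "#META" = {
        if (length(f) != 3) bad("expected #META,key,value")
        meta[[f[[2]]]] <- f[[3]]
      },
      "#TRIAL_START" = {
        if (length(f) != 2 || is.na(as.integer(f[[2]]))) bad("bad trial index")
        if (!is.na(cur_trial)) bad("nested trial start")
        cur_trial <- as.integer(f[[2]])
      },
      "#TRIAL_END" = {
        if (length(f) != 2 || is.na(as.integer(f[[2]]))) bad("bad trial index")
        if (is.na(cur_trial) || as.integer(f[[2]]) != cur_trial) {
          bad("unmatched trial end")
        }
        cur_trial <- NA_integer_
      },
      "S" = {
        if (length(f) != 5) bad("expected S,t,x,y,valid")
        if (is.na(cur_trial)) bad("sample outside a trial")
        v <- parse_num(f[2:4])
        if (is.na(v[1]) || !f[[5]] %in% c("0", "1")) bad("bad sample fields")
        st[[length(st) + 1L]] <- list(trial = cur_trial, t = v[1], x = v[2],
                                      y = v[3], valid = f[[5]] == "1")
      },
      "M" = {
        if (length(f) != 3) bad("expected M,t,text")
        if (is.na(cur_trial)) bad("message outside a trial")
        tt <- parse_num(f[[2]])
        if (is.na(tt)) bad("bad message timestamp")
        sm[[length(sm) + 1L]] <- list(trial = cur_trial, t = tt,
                                      text = unescape_msg(f[[3]]))
      },
      bad("unknown record type")
    )
  }
  if (!is.na(cur_trial)) {
    abort(sprintf("parse error: trial %d never ended", cur_trial))
  }
  samples <- if (length(st)) dplyr::bind_rows(st) else
    tibble::tibble(trial = integer(), t = numeric(), x = numeric(),
                   y = numeric(), valid = logical())
  messages <- if (length(sm)) dplyr::bind_rows(sm) else NULL
  if (is.null(meta$nominal_rate)) abort("missing #META,nominal_rate record")
  geom <- NULL
  if (!is.null(meta$viewing_distance_cm)) {
    res <- as.numeric(strsplit(meta$resolution, "x", fixed = TRUE)[[1]])
    geom <- screen_geometry(parse_num(meta$viewing_distance_cm),
                            parse_num(meta$pixels_per_cm), res)
  }
  gaze_recording(samples, messages, nominal_rate = parse_num(meta$nominal_rate),
                 geometry = geom)
}

#' Write calibration samples to CSV
#'
#' Rows `C,<t_ms>,<U>,<V>,<target_x_deg>,<target_y_deg>`.
#'
#' @param samples Data frame with columns `t`, `U`, `V`, `target_x`,
#'   `target_y`.
#' @param path Output file path.
#' @return `samples`, invisibly.
#' @export
write_calibration_csv <- function(samples, path) {
  stopifnot(all(c("t", "U", "V", "target_x", "target_y") %in% names(samples)))
  lines <- sprintf("C,%s,%s,%s,%s,%s", fmt_num(samples$t), fmt_num(samples$U),
                   fmt_num(samples$V), fmt_num(samples$target_x),
                   fmt_num(samples$target_y))
  writeLines(lines, path)
  invisible(samples)
}

#' Read calibration samples from CSV
#'
#' @param path Input file path (rows as written by
#'   [write_calibration_csv()]).
#' @return A tibble with columns `t`, `U`, `V`, `target_x`, `target_y`.
#' @export
read_calibration_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, ",", fixed = TRUE)
  badi <- which(vapply(parts, function(p) length(p) != 6 || p[[1]] != "C",
                       logical(1)))
  if (length(badi)) {
    abort(sprintf("parse error at line %d: expected C,t,U,V,tx,ty", badi[1]))
  }
  m <- do.call(rbind, lapply(parts, function(p) parse_num(p[2:6])))
  tibble::tibble(t = m[, 1], U = m[, 2], V = m[, 3],
                 target_x = m[, 4], target_y = m[, 5])
}
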