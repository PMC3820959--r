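#' Construct an inertial recording
#'
#' An `inertial_recording` is a uniformly sampled six-channel inertial
#' sensor stream in the body-fixed coordinate system (x toward the head,
#' y toward the right, z into the body): three acceleration components in
#' g and three angular-velocity components (roll, pitch, yaw rates about
#' x, y, z) in degrees per second, with a per-sample time stamp in seconds.
#'
#' @param t numeric vector of sample times in seconds, strictly increasing
#'   and uniform at `sample_rate`.
#' @param a_x,a_y,a_z acceleration components in g.
#' @param w_roll,w_pitch,w_yaw angular-velocity components in degrees/s.
#' @param sample_rate sampling frequency in Hz (default 100).
#' @param dog_id,breed,session_index measurement metadata.
#' @return an object of class `inertial_recording`: a list with the seven
#'   channel vectors, `sample_rate` and a `meta` list.
#' @export
inertial_recording <- function(t, a_x, a_y, a_z, w_roll, w_pitch, w_yaw,
                               sample_rate = 100,
                               dog_id = NA_character_, breed = NA_character_,
                               session_index = NA_integer_) {
  n <- length(t)
  chans <- list(t = t, a_x = a_x, a_y = a_y, a_z = a_z,
                w_roll = w_roll, w_pitch = w_pitch, w_yaw = w_yaw)
  lens <- vapply(chans, length, integer(1))
  if (any(lens != n)) {
    stop("all channels must have the same length", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("sample_rate must be a positive scalar", call. = FALSE)
  }
  if (n > 0 && anyNA(t)) stop("timestamps must be finite", call. = FALSE)
  if (n > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) {
      stop("timestamps must be strictly increasing", call. = FALSE)
    }
    if (any(abs(dt - 1 / sample_rate) > 1e-9)) {
      stop("timestamps are not uniform at ", sample_rate, " Hz", call. = FALSE)
    }
  }
  structure(
    c(chans, list(sample_rate = sample_rate,
                  meta = list(dog_id = dog_id, breed = breed,
                              session_index = session_index))),
    class = "inertial_recording")
}

#' @export
length.inertial_recording <- function(x) length(x$t)

#' @export
print.inertial_recording <- function(x, ...) {
  cat(sprintf("<inertial_recording> %d samples @ %g Hz (%.2f s)\n",
              length(x), x$sample_rate,
              if (length(x)) length(x) / x$sample_rate else 0))
  cat(sprintf("  dog=%s breed=%s session=%s\n", x$meta$dog_id, x$meta$breed,
              x$meta$session_index))
  invisible(x)
}

#' Read and write raw inertial recordings
#'
#' Recordings are stored as delimited text with seven numeric columns
#' `t, ax, ay, az, wr, wp, wy` (seconds, g, degrees/s). Comment lines
#' starting with `#` and an optional header row are skipped.
#'
#' @param path file path.
#' @param sample_rate expected sampling frequency in Hz.
#' @param dog_id,breed,session_index metadata attached to the recording.
#' @return `read_recording()` returns an [inertial_recording()];
#'   `write_recording()` returns `path` invisibly.
#' @export
read_recording <- function(path, sample_rate = 100,
                           dog_id = NA_character_, breed = NA_character_,
                           session_index = NA_integer_) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) > 0 && grepl("[A-Za-z]", lines[[1L]])) {
    lines <- lines[-1L]  # header row
  }
  if (length(lines) == 0L) {
    return(inertial_recording(numeric(0), numeric(0), numeric(0), numeric(0),
                              numeric(0), numeric(0), numeric(0),
                              sample_rate, dog_id, breed, session_index))
  }
  fields <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    stop("malformed row at line ", which(nf != 7L)[1L],
         ": expected 7 comma-separated values", call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1L, anyNA))[1L]
    stop("malformed row at line ", bad, ": non-numeric value", call. = FALSE)
  }
  inertial_recording(m[, 1L], m[, 2L], m[, 3L], m[, 4L],
                     m[, 5L], m[, 6L], m[, 7L],
                     sample_rate, dog_id, breed, session_index)
}

#' @param rec an [inertial_recording()].
#' @rdname read_recording
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "inertial_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# units: t seconds, ax/ay/az g, wr/wp/wy deg/s",
               "t,ax,ay,az,wr,wp,wy"), con)
  m <- cbind(rec$t, rec$a_x, rec$a_y, rec$a_z,
             rec$w_roll, rec$w_pitch, rec$w_yaw)
  if (nrow(m) > 0) {
    writeLines(apply(format(m, digits = 15, trim = TRUE, scientific = FALSE),
                     1L, paste, collapse = ","), con)
  }
  invisible(path)
}

#' Construct a behaviour label track
#'
#' A label track is an ordered set of non-overlapping half-open time
#' intervals `[start, end)` in seconds, each tagged with one of the seven
#' behaviour categories. Gaps between intervals are allowed (annotation may
#' be interrupted).
#'
#' @param start,end interval bounds in seconds, `end > start`.
#' @param category character vector of behaviour categories.
#' @param coder_id identifier of the human coder (or simulator) that
#'   produced the track.
#' @return an object of class `label_track`: a data.frame with columns
#'   `start`, `end`, `category` plus a `coder_id` attribute.
#' @export
label_track <- function(start = numeric(0), end = numeric(0),
                        category = character(0), coder_id = "coder") {
  stopifnot(length(start) == length(end), length(end) == length(category))
  category <- as.character(category)
  if (length(start) > 0) {
    if (any(end <= start)) {
      stop("label intervals must satisfy end > start", call. = FALSE)
    }
    behavior_factor(category)  # validates names
    o <- order(start)
    start <- start[o]; end <- end[o]; category <- category[o]
    if (any(start[-1L] < end[-length(end)] - 1e-12)) {
      stop("label intervals overlap", call. = FALSE)
    }
  }
  structure(data.frame(start = as.numeric(start), end = as.numeric(end),
                       category = category, stringsAsFactors = FALSE),
            coder_id = coder_id,
            class = c("label_track", "data.frame"))
}

#' Read and write SRT behaviour annotations
#'
#' Behaviour annotations are exchanged as SubRip (SRT) subtitle files: each
#' cue spans a time interval and its text names one behaviour category.
#' Cue texts are matched case-insensitively after trimming; non-canonical
#' texts must be translated through `category_map` (there are no built-in
#' aliases).
#'
#' @param path SRT file path.
#' @param category_map named character vector mapping cue text (lower case)
#'   to a canonical category, e.g. `c(run = "gallop")`. Canonical names are
#'   always accepted.
#' @param coder_id coder identifier stored on the returned track.
#' @return `read_labels()` returns a [label_track()]; `write_labels()`
#'   returns `path` invisibly.
#' @export
read_labels <- function(path, category_map = NULL, coder_id = "coder") {
  lines <- readLines(path, warn = FALSE)
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  blocks <- lapply(blocks, function(b) b[nzchar(trimws(b))])
  blocks <- blocks[lengths(blocks) > 0L]
  starts <- ends <- numeric(0)
  cats <- character(0)
  time_re <- "^(\\d{2}):(\\d{2}):(\\d{2})[,.](\\d{3})\\s*-+>\\s*(\\d{2}):(\\d{2}):(\\d{2})[,.](\\d{3})"
  for (b in blocks) {
    ti <- grep("-->", b)
    if (length(ti) != 1L) {
      stop("malformed SRT cue (no timing line): ",
           paste(b, collapse = " | "), call. = FALSE)
    }
    m <- regmatches(b[ti], regexec(time_re, b[ti]))[[1L]]
    if (length(m) != 9L) {
      stop("malformed SRT timing line: ", b[ti], call. = FALSE)
    }
    v <- as.numeric(m[-1L])
    s <- v[1L] * 3600 + v[2L] * 60 + v[3L] + v[4L] / 1000
    e <- v[5L] * 3600 + v[6L] * 60 + v[7L] + v[8L] / 1000
    txt <- trimws(paste(b[seq.int(ti + 1L, length(b))], collapse = " "))
    if (ti == length(b) || !nzchar(txt)) {
      stop("SRT cue has no text at ", b[ti], call. = FALSE)
    }
    key <- tolower(txt)
    cat_name <- if (key %in% behavior_categories()) {
      key
    } else if (!is.null(category_map) && key %in% names(category_map)) {
      unname(category_map[[key]])
    } else {
      stop("unmapped cue text: \"", txt, "\"", call. = FALSE)
    }
    starts <- c(starts, s); ends <- c(ends, e); cats <- c(cats, cat_name)
  }
  label_track(starts, ends, cats, coder_id = coder_id)
}

#' @param track a [label_track()].
#' @rdname read_labels
#' @export
write_labels <- function(track, path) {
  stopifnot(inherits(track, "label_track"))
  fmt_time <- function(s) {
    ms <- round(s * 1000)
    sprintf("%02d:%02d:%02d,%03d", ms %/% 3600000, (ms %/% 60000) %% 60,
            (ms %/% 1000) %% 60, ms %% 1000)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(track))) {
    writeLines(c(as.character(i),
                 paste(fmt_time(track$start[i]), "-->", fmt_time(track$end[i])),
                 track$category[i], ""), con)
  }
  invisible(path)
}

#' Trim a safety margin off every labelled interval
#'
#' To guard against imprecise annotation boundaries, a margin is neglected
#' at both the beginning and the end of every labelled interval before
#' windows are cut: `[s, e)` becomes `[s + margin, e - margin)`, and
#' intervals no longer than `2 * margin` are dropped entirely. The default
#' one-second margin matches the pre-processing used when building training
#' data from human-coded subtitles.
#'
#' Note the operation is not idempotent: applying it twice trims twice.
#'
#' @param track a [label_track()].
#' @param margin seconds to trim from each side (default 1).
#' @return the trimmed [label_track()].
#' @export
apply_margin <- function(track, margin = 1.0) {
  stopifnot(inherits(track, "label_track"))
  if (!is.numeric(margin) || length(margin) != 1L || margin < 0) {
    stop("margin must be a non-negative scalar", call. = FALSE)
  }
  keep <- (track$end - track$start) > 2 * margin
  label_track(track$start[keep] + margin, track$end[keep] - margin,
              track$category[keep], coder_id = attr(track, "coder_id"))
}
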