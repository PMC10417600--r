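#' Detection streams
#'
#' A detection stream is a data frame holding every bounding box seen by the
#' chamber cameras, one row per box, in the canonical CSV dialect:
#' \code{experiment_id, replicate, day, session, compartment, frame_index,
#' timestamp_s, x_min, y_min, x_max, y_max}.  A frame in which a camera saw no
#' bird is kept as an explicit record with \code{NA} box fields -- empty frames
#' are first-class data (bird count 0), not missing data, which is what makes
#' permanence time a sum over \emph{all} frames.
#'
#' Stream-level metadata is carried in attributes: \code{fps} (capture rate of
#' the underlying video), \code{frame_step} (spacing of retained frame indices
#' after down-sampling; the effective rate is \code{fps / frame_step}) and
#' \code{frame_size}.
#'
#' @param df data frame in the dialect above (box columns may be \code{NA} on
#'   empty-frame rows).
#' @param fps capture frame rate of the source video (frames per second).
#' @param frame_step spacing between retained frame indices (1 for a raw
#'   stream; \code{downsample} multiplies it).
#' @param frame_size \code{c(width, height)} in pixels.
#' @return a \code{detection_stream}: the canonicalized data frame (sorted by
#'   experiment, replicate, day, session, compartment, frame index, box
#'   coordinates) with the metadata attributes above.
#' @export
detection_stream <- function(df, fps = 30, frame_step = 1L,
                             frame_size = default_frame_size()) {
  required <- c("experiment_id", "replicate", "day", "session", "compartment",
                "frame_index", "timestamp_s",
                "x_min", "y_min", "x_max", "y_max")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("detection stream is missing columns: ",
         paste(missing_cols, collapse = ", "))
  df <- df[required]
  if (nrow(df)) {
    if (any(df$frame_index < 0, na.rm = TRUE))
      stop("frame_index must be non-negative")
    # derive timestamps from frame_index / fps when absent
    no_ts <- is.na(df$timestamp_s)
    df$timestamp_s[no_ts] <- df$frame_index[no_ts] / fps
    df <- df[order(df$experiment_id, df$replicate, df$day, df$session,
                   df$compartment, df$frame_index, df$x_min, df$y_min), ]
  }
  rownames(df) <- NULL
  structure(df, fps = fps, frame_step = as.integer(frame_step),
            frame_size = frame_size,
            class = c("detection_stream", "data.frame"))
}

stream_meta <- function(stream) {
  list(fps = attr(stream, "fps") %||% 30,
       frame_step = attr(stream, "frame_step") %||% 1L,
       frame_size = attr(stream, "frame_size") %||% default_frame_size())
}

#' Effective frame rate of a stream
#'
#' Capture rate divided by the retained frame spacing; this is the divisor
#' used when converting summed per-frame counts into permanence time.
#'
#' @param stream a \code{detection_stream}.
#' @return frames per second after down-sampling.
#' @export
effective_fps <- function(stream) {
  m <- stream_meta(stream)
  m$fps / m$frame_step
}

#' @export
print.detection_stream <- function(x, ...) {
  m <- stream_meta(x)
  n_frames <- nrow(unique(as.data.frame(x)[c("experiment_id", "replicate",
                                             "day", "session", "compartment",
                                             "frame_index")]))
  cat(sprintf(
    "<detection_stream> %d box records over %d frame records, %g fps (step %d, effective %g fps)\n",
    sum(!is.na(x$x_min)), n_frames, m$fps, m$frame_step, effective_fps(x)))
  invisible(x)
}

csv_header <- c("experiment_id", "replicate", "day", "session", "compartment",
                "frame_index", "timestamp_s",
                "x_min", "y_min", "x_max", "y_max")

#' Read a detection CSV
#'
#' Reads the canonical detection dialect (see \code{\link{detection_stream}}).
#' Empty-frame records (all four box fields empty) are preserved.  Rows whose
#' box violates the box invariants (e.g. \code{x_min >= x_max}) are dropped
#' with a warning stating how many were rejected; if the rejection empties a
#' frame, an explicit empty-frame record is kept in its place.  A structurally
#' malformed row (wrong field count, non-numeric coordinates, partially empty
#' box) is an error naming the offending line.
#'
#' @param path path to a CSV file with the canonical header.
#' @param fps,frame_size stream metadata (see \code{\link{detection_stream}}).
#' @return a \code{\link{detection_stream}}.
#' @export
read_detection_csv <- function(path, fps = 30, frame_size = default_frame_size()) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- count.fields(path, sep = ",", quote = "\"", blank.lines.skip = FALSE)
  if (length(nf) == 0) stop("empty file (no header): ", path)
  bad <- which(!is.na(nf) & nf != length(csv_header))
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s: expected %d fields, found %d",
                 bad[1], path, length(csv_header), nf[bad[1]]))
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(df), csv_header))
    stop("unexpected header in ", path, "; expected: ",
         paste(csv_header, collapse = ","))
  if (nrow(df) == 0)
    return(detection_stream(empty_stream_frame(), fps = fps,
                            frame_size = frame_size))
  num_cols <- c("experiment_id", "replicate", "day", "frame_index",
                "timestamp_s", "x_min", "y_min", "x_max", "y_max")
  for (cc in num_cols) {
    raw <- df[[cc]]
    val <- suppressWarnings(as.numeric(raw))
    garbled <- which(is.na(val) & !(raw == "" | raw == "NA"))
    if (length(garbled))
      stop(sprintf("malformed row at line %d of %s: non-numeric value '%s' in %s",
                   garbled[1] + 1L, path, raw[garbled[1]], cc))
    df[[cc]] <- val
  }
  df$frame_index <- as.integer(df$frame_index)
  box_na <- is.na(df[c("x_min", "y_min", "x_max", "y_max")])
  partial <- which(rowSums(box_na) %in% 1:3)
  if (length(partial))
    stop(sprintf("malformed row at line %d of %s: partially empty box fields",
                 partial[1] + 1L, path))
  has_box <- rowSums(box_na) == 0
  ok <- !has_box
  ok[has_box] <- valid_boxes(df[has_box, , drop = FALSE], frame_size)
  if (any(!ok)) {
    warning(sprintf("%d box record(s) rejected (invalid box geometry)",
                    sum(!ok)), call. = FALSE)
    rejected <- df[!ok, , drop = FALSE]
    df <- df[ok, , drop = FALSE]
    # keep an empty-frame record for frames emptied by the rejection
    key <- function(d) do.call(paste, c(d[c("experiment_id", "replicate", "day",
                                            "session", "compartment",
                                            "frame_index")], sep = "\r"))
    orphan <- rejected[!duplicated(key(rejected)) &
                       !(key(rejected) %in% key(df)), , drop = FALSE]
    if (nrow(orphan)) {
      orphan[c("x_min", "y_min", "x_max", "y_max")] <- NA_real_
      df <- rbind(df, orphan)
    }
  }
  detection_stream(df, fps = fps, frame_size = frame_size)
}

empty_stream_frame <- function() {
  data.frame(experiment_id = numeric(0), replicate = numeric(0),
             day = numeric(0), session = character(0),
             compartment = character(0), frame_index = integer(0),
             timestamp_s = numeric(0), x_min = numeric(0), y_min = numeric(0),
             x_max = numeric(0), y_max = numeric(0))
}

fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 12)
  out[is.na(x)] <- ""
  trimws(out)
}

#' Write a detection stream as canonical CSV
#'
#' Writes the canonical dialect; numbers are formatted so that
#' \code{write_detection_csv(read_detection_csv(f))} reproduces a canonical
#' file byte for byte (records sorted, fixed numeric formatting, empty box
#' fields for empty frames).
#'
#' @param stream a \code{\link{detection_stream}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_detection_csv <- function(stream, path) {
  df <- as.data.frame(stream)
  out <- data.frame(lapply(df[csv_header], function(col)
    if (is.numeric(col)) fmt_num(col) else as.character(col)),
    check.names = FALSE)
  names(out) <- csv_header
  con <- file(path, "wb")  # binary: stable newlines across platforms
  on.exit(close(con))
  writeLines(paste(csv_header, collapse = ","), con)
  if (nrow(out))
    writeLines(do.call(paste, c(out, sep = ",")), con)
  invisible(path)
}

#' Down-sample a detection stream
#'
#' Keeps frames whose original index is congruent to 0 modulo
#' \code{frame_step * factor}, mirroring the reduction of 30 fps footage to
#' 15 fps before analysis.  The effective frame rate recorded on the stream
#' becomes \code{fps / (frame_step * factor)}.  Composition holds:
#' \code{downsample(downsample(s, a), b)} equals \code{downsample(s, a * b)}.
#'
#' @param stream a \code{\link{detection_stream}}.
#' @param factor positive integer decimation factor.
#' @return the decimated \code{detection_stream}.
#' @export
downsample <- function(stream, factor) {
  if (length(factor) != 1 || is.na(factor) || factor < 1 ||
      factor != round(factor))
    stop("factor must be a positive integer")
  m <- stream_meta(stream)
  step <- m$frame_step * as.integer(factor)
  keep <- stream$frame_index %% step == 0
  detection_stream(as.data.frame(stream)[keep, , drop = FALSE],
                   fps = m$fps, frame_step = step, frame_size = m$frame_size)
}

hms_to_s <- function(x) {
  p <- strsplit(x, ":", fixed = TRUE)
  vapply(p, function(v) sum(as.numeric(v) * c(3600, 60, 1)[seq_along(v)]), 0)
}

#' Daily observation windows
#'
#' The two 2-hour daily monitoring periods: 09:30-11:30 and 15:00-17:00 by
#' default, chosen to average over natural diurnal behavior variation.
#' Windows are half-open \code{[start, end)} so a frame falling exactly on a
#' boundary is counted once.
#'
#' @param morning,afternoon character \code{c(start, end)} times of day
#'   (\code{"HH:MM"}).
#' @return data frame with columns \code{session}, \code{start_s},
#'   \code{end_s} (seconds since midnight).
#' @export
observation_windows <- function(morning = c("09:30", "11:30"),
                                afternoon = c("15:00", "17:00")) {
  data.frame(session = c("morning", "afternoon"),
             start_s = c(hms_to_s(morning[1]), hms_to_s(afternoon[1])),
             end_s = c(hms_to_s(morning[2]), hms_to_s(afternoon[2])))
}

#' Restrict a stream to observation windows
#'
#' Keeps only frames whose time of day falls inside one of the (non
#' overlapping) half-open windows \code{[start_s, end_s)}, and rewrites the
#' \code{session} column to the matched window's label.  Timestamps are
#' interpreted as seconds since midnight of day 1, so a multi-day continuous
#' recording is windowed day by day.
#'
#' @param stream a \code{\link{detection_stream}}.
#' @param windows data frame as returned by \code{\link{observation_windows}}.
#' @return the windowed \code{detection_stream}; frame order is preserved and
#'   no frames are fabricated.
#' @export
select_windows <- function(stream, windows) {
  if (nrow(windows) > 1) {
    w <- windows[order(windows$start_s), ]
    if (any(w$end_s[-nrow(w)] > w$start_s[-1]))
      stop("observation windows overlap")
  }
  if (any(windows$end_s <= windows$start_s)) stop("window end must be after start")
  m <- stream_meta(stream)
  if (nrow(windows) == 0 || nrow(stream) == 0)
    return(detection_stream(empty_stream_frame(), fps = m$fps,
                            frame_step = m$frame_step,
                            frame_size = m$frame_size))
  tod <- stream$timestamp_s %% 86400
  idx <- rep(NA_integer_, length(tod))
  for (i in seq_len(nrow(windows)))
    idx[tod >= windows$start_s[i] & tod < windows$end_s[i]] <- i
  out <- as.data.frame(stream)[!is.na(idx), , drop = FALSE]
  out$session <- windows$session[idx[!is.na(idx)]]
  detection_stream(out, fps = m$fps, frame_step = m$frame_step,
                   frame_size = m$frame_size)
}
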