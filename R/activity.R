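#' Unrest index parameters
#'
#' @param k dimensionless proportionality factor set by the camera's field of
#'   view; 1 for the chamber's 90-degree overhead cameras.
#' @param empty_frame_policy what to do when one frame of a consecutive pair
#'   holds no detections: \code{"missing"} (default) marks the pair value
#'   \code{NA} so it is excluded from aggregation -- absence of birds is not
#'   stillness -- while \code{"zero"} scores it 0 for sensitivity analysis.
#' @return an \code{unrest_params} list.
#' @export
unrest_params <- function(k = 1, empty_frame_policy = c("missing", "zero")) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) stop("k must be > 0")
  structure(list(k = k,
                 empty_frame_policy = match.arg(empty_frame_policy)),
            class = "unrest_params")
}

#' Directed set distance between centroid sets
#'
#' The directed Hausdorff distance: the largest distance from a point of
#' \code{a} to its nearest neighbor in \code{b}.  Asymmetric by construction;
#' the unrest index takes the maximum of the two directions.
#'
#' @param a,b matrices or data frames of points (columns x, y), both
#'   non-empty.
#' @return distance in pixels.
#' @examples
#' directed_set_distance(rbind(c(0, 0), c(3, 4)), rbind(c(0, 0)))  # 5
#' directed_set_distance(rbind(c(0, 0)), rbind(c(0, 0), c(3, 4)))  # 0
#' @export
directed_set_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("point sets must be non-empty")
  d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
  sqrt(max(apply(d2, 1, min)))
}

hausdorff <- function(a, b) {
  max(directed_set_distance(a, b), directed_set_distance(b, a))
}

#' Unrest index between two frames
#'
#' Identity-free activity measure for a pair of consecutive frames of one
#' compartment: \code{k} times the symmetric Hausdorff distance between the
#' two frames' detection centroid sets.  Because it compares centroid
#' \emph{sets}, it requires no tracking of individual birds.  It is zero iff
#' the two centroid sets coincide, scales linearly with \code{k} and with any
#' rescaling of the pixel coordinates, and is invariant to a common
#' translation of both frames.
#'
#' @param f_i,f_prev data frames of box records for the two frames (rows with
#'   \code{NA} box fields denote an empty frame); both must come from the same
#'   compartment.
#' @param params an \code{\link{unrest_params}}.
#' @return index value in (k-scaled) pixels, or \code{NA} when a side is
#'   empty under the \code{"missing"} policy.
#' @export
unrest_index <- function(f_i, f_prev, params = unrest_params()) {
  comp_i <- unique(f_i$compartment)
  comp_p <- unique(f_prev$compartment)
  if (length(comp_i) > 1 || length(comp_p) > 1 ||
      (length(comp_i) == 1 && length(comp_p) == 1 && comp_i != comp_p))
    stop("frames must come from a single, common compartment")
  a <- centroid(f_i[!is.na(f_i$x_min), , drop = FALSE])
  b <- centroid(f_prev[!is.na(f_prev$x_min), , drop = FALSE])
  if (nrow(a) == 0 || nrow(b) == 0)
    return(if (params$empty_frame_policy == "zero") 0 else NA_real_)
  params$k * hausdorff(as.matrix(a), as.matrix(b))
}

#' Unrest series over a detection stream
#'
#' Computes the unrest index for every pair of consecutive retained frames
#' within each contiguous segment of a stream.  Segments are delimited by the
#' stream keys (experiment, replicate, day, session, compartment) and by
#' gaps in the frame index: two frames form a pair only when their indices
#' differ by exactly the stream's \code{frame_step}, so no pair ever spans an
#' observation-window gap.
#'
#' @param stream a \code{\link{detection_stream}}.
#' @param params an \code{\link{unrest_params}}.
#' @return an \code{unrest_series} data frame: one row per consecutive frame
#'   pair with the segment keys, \code{pair_index}, \code{value} (k-scaled
#'   pixels, \code{NA} when suppressed by the empty-frame policy),
#'   \code{n_boxes_i} and \code{n_boxes_prev}.
#' @export
unrest_series <- function(stream, params = unrest_params()) {
  step <- stream_meta(stream)$frame_step
  df <- as.data.frame(stream)
  keys <- c("experiment_id", "replicate", "day", "session", "compartment")
  empty <- cbind(df[0, keys, drop = FALSE],
                 data.frame(pair_index = integer(0), frame_index = integer(0),
                            value = numeric(0), n_boxes_i = integer(0),
                            n_boxes_prev = integer(0)))
  if (nrow(df) == 0) return(structure(empty, class = c("unrest_series", "data.frame")))
  seg <- interaction(df[keys], drop = TRUE)
  out <- lapply(split(df, seg), function(d) {
    idx <- sort(unique(d$frame_index))
    if (length(idx) < 2) return(NULL)
    has_box <- !is.na(d$x_min)
    cents <- split(centroid(d[has_box, , drop = FALSE]),
                   factor(d$frame_index[has_box], levels = idx))
    counts <- vapply(cents, nrow, 0L)
    pairs <- which(diff(idx) == step)
    if (!length(pairs)) return(NULL)
    vals <- vapply(pairs, function(j) {
      a <- cents[[j]]; b <- cents[[j + 1]]
      if (nrow(a) == 0 || nrow(b) == 0) {
        if (params$empty_frame_policy == "zero") 0 else NA_real_
      } else params$k * hausdorff(as.matrix(a), as.matrix(b))
    }, 0)
    cbind(d[rep(1, length(pairs)), keys, drop = FALSE],
          data.frame(pair_index = seq_along(pairs),
                     frame_index = idx[pairs + 1],
                     value = vals,
                     n_boxes_i = unname(counts[pairs + 1]),
                     n_boxes_prev = unname(counts[pairs])))
  })
  out <- do.call(rbind, c(list(empty), out))
  rownames(out) <- NULL
  structure(out, class = c("unrest_series", "data.frame"))
}

#' Aggregate unrest by treatment cell
#'
#' Summarizes an unrest series per (light, temperature) treatment cell.  The
#' statistical unit is the observation window: the series is first averaged
#' within each 2-hour window (experiment x replicate x day x session x
#' compartment), then the window means are summarized per cell.  This keeps
#' replicate counts balanced across cells and avoids treating the thousands
#' of highly autocorrelated frame pairs inside a window as independent.
#'
#' @param series an \code{\link{unrest_series}}.
#' @param design an \code{\link{epc_design}} used to map (experiment,
#'   compartment) to (light, temperature).
#' @return list with \code{windows} (one row per window: keys, light,
#'   temperature, \code{mean_unrest_px}, \code{n_pairs}) and \code{cells}
#'   (per light x temperature: \code{mean}, \code{sd}, \code{n} window
#'   means; cells with no data are absent, never zero-filled).
#' @export
aggregate_unrest <- function(series, design) {
  ann <- annotate_treatments(as.data.frame(series), design)
  keys <- c("experiment_id", "replicate", "day", "session", "compartment",
            "light", "temperature")
  ok <- !is.na(ann$value)
  if (!any(ok)) stop("unrest series holds no usable (non-missing) pairs")
  win <- aggregate(ann$value[ok], ann[ok, keys, drop = FALSE], mean)
  names(win)[ncol(win)] <- "mean_unrest_px"
  win$n_pairs <- aggregate(ann$value[ok], ann[ok, keys, drop = FALSE],
                           length)$x
  cells <- do.call(rbind, lapply(
    split(win, win[c("light", "temperature")], drop = TRUE),
    function(d) data.frame(light = d$light[1], temperature = d$temperature[1],
                           mean = mean(d$mean_unrest_px),
                           sd = sd(d$mean_unrest_px), n = nrow(d))))
  rownames(cells) <- NULL
  list(windows = win[order(win$experiment_id, win$replicate, win$day,
                           win$session, win$compartment), ],
       cells = cells[order(cells$temperature, cells$light), ])
}
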