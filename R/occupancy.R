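#' Per-frame bird counts
#'
#' Collapses a detection stream to one record per (frame, compartment) with
#' the number of detected boxes; empty-frame records yield count 0.
#'
#' @param stream a \code{\link{detection_stream}}.
#' @return a \code{count_series} data frame: stream keys, \code{frame_index},
#'   \code{timestamp_s} and \code{count}, carrying the stream's effective fps
#'   as an attribute.
#' @export
frame_counts <- function(stream) {
  df <- as.data.frame(stream)
  keys <- c("experiment_id", "replicate", "day", "session", "compartment",
            "frame_index")
  if (nrow(df) == 0) {
    out <- cbind(df[0, keys, drop = FALSE],
                 data.frame(timestamp_s = numeric(0), count = integer(0)))
  } else {
    out <- aggregate(list(count = !is.na(df$x_min)), df[keys], sum)
    out$count <- as.integer(out$count)
    out$timestamp_s <- df$timestamp_s[match(
      do.call(paste, c(out[keys], sep = "\r")),
      do.call(paste, c(df[keys], sep = "\r")))]
    out <- out[order(out$experiment_id, out$replicate, out$day, out$session,
                     out$compartment, out$frame_index),
               c(keys[1:5], "frame_index", "timestamp_s", "count")]
    rownames(out) <- NULL
  }
  structure(out, effective_fps = effective_fps(stream),
            class = c("count_series", "data.frame"))
}

#' Door-edge duplicate policy
#'
#' Near the automatic doors a bird can protrude into the neighboring
#' compartment and be detected by both cameras at once.  The manual
#' validation rule keeps the detection in the compartment holding the bird's
#' head; heads are unobservable to the count pipeline, so the automated proxy
#' pairs door-edge boxes across adjacent compartments and discards the
#' smaller-area member of each pair (the body remnant).
#'
#' @param margin distance in pixels from the shared door edge within which a
#'   box is a duplicate candidate.
#' @param mode \code{"off"} (default, matching the automatic pipeline, which
#'   over-counted only 1.23\% of validated frames) or \code{"suppress"}.
#' @return an \code{edge_policy} list.
#' @export
edge_policy <- function(margin = 20, mode = c("off", "suppress")) {
  if (margin < 0) stop("margin must be >= 0")
  structure(list(margin = margin, mode = match.arg(mode)),
            class = "edge_policy")
}

#' Default door geometry
#'
#' Which image edge of each compartment abuts which neighbor.  The default
#' lays the compartments out in the chain A-B-C with doors on the x edges;
#' the geometry is always declared, never guessed from pixel content.
#'
#' @return data frame with one row per door: \code{comp_1}, \code{edge_1},
#'   \code{comp_2}, \code{edge_2} (edges are \code{"left"}, \code{"right"},
#'   \code{"top"}, \code{"bottom"}).
#' @export
default_doors <- function() {
  data.frame(comp_1 = c("A", "B"), edge_1 = c("right", "right"),
             comp_2 = c("B", "C"), edge_2 = c("left", "left"))
}

edge_distance <- function(df, edge, frame_size) {
  switch(edge,
         left   = df$x_min,
         right  = frame_size[[1]] - df$x_max,
         top    = df$y_min,
         bottom = frame_size[[2]] - df$y_max,
         stop("unknown edge: ", edge))
}

#' Suppress cross-compartment duplicate detections
#'
#' For each scene (set of simultaneous frames across compartments) and each
#' declared door, boxes lying within \code{policy$margin} of the shared edge
#' on both sides are greedily paired, nearest combined edge-distance first,
#' and the smaller-area member of each pair is removed -- at most one removal
#' per pair, so no count ever increases.  With \code{mode = "off"} the stream
#' is returned unchanged.
#'
#' @param stream a \code{\link{detection_stream}} (synchronized across
#'   compartments by \code{frame_index}).
#' @param policy an \code{\link{edge_policy}}.
#' @param doors door geometry (see \code{\link{default_doors}}).
#' @return the filtered \code{detection_stream}; frames emptied by the
#'   suppression keep an explicit empty-frame record.
#' @export
resolve_duplicates <- function(stream, policy = edge_policy(),
                               doors = default_doors()) {
  if (policy$mode == "off") return(stream)
  m <- stream_meta(stream)
  df <- as.data.frame(stream)
  if (nrow(df) == 0) return(stream)
  has_box <- !is.na(df$x_min)
  drop <- rep(FALSE, nrow(df))
  scene_key <- do.call(paste, c(df[c("experiment_id", "replicate", "day",
                                     "session", "frame_index")], sep = "\r"))
  for (d in seq_len(nrow(doors))) {
    for (side in 1:2) {
      comp <- doors[[paste0("comp_", side)]][d]
      edge <- doors[[paste0("edge_", side)]][d]
      sel <- has_box & df$compartment == comp
      dist <- rep(Inf, nrow(df))
      dist[sel] <- edge_distance(df[sel, , drop = FALSE], edge, m$frame_size)
      if (side == 1) { c1 <- which(sel & dist <= policy$margin); d1 <- dist }
      else           { c2 <- which(sel & dist <= policy$margin); d2 <- dist }
    }
    if (!length(c1) || !length(c2)) next
    for (sk in intersect(unique(scene_key[c1]), unique(scene_key[c2]))) {
      i1 <- setdiff(c1[scene_key[c1] == sk], which(drop))
      i2 <- setdiff(c2[scene_key[c2] == sk], which(drop))
      while (length(i1) && length(i2)) {
        cost <- outer(d1[i1], d2[i2], `+`)
        best <- which(cost == min(cost), arr.ind = TRUE)[1, ]
        pair <- c(i1[best[1]], i2[best[2]])
        area <- (df$x_max[pair] - df$x_min[pair]) *
                (df$y_max[pair] - df$y_min[pair])
        drop[pair[which.min(area)]] <- TRUE
        i1 <- i1[-best[1]]; i2 <- i2[-best[2]]
      }
    }
  }
  if (!any(drop)) return(stream)
  removed <- df[drop, , drop = FALSE]
  kept <- df[!drop, , drop = FALSE]
  fkey <- function(x) do.call(paste, c(x[c("experiment_id", "replicate", "day",
                                           "session", "compartment",
                                           "frame_index")], sep = "\r"))
  orphan <- removed[!duplicated(fkey(removed)) &
                    !(fkey(removed) %in% fkey(kept)), , drop = FALSE]
  if (nrow(orphan)) {
    orphan[c("x_min", "y_min", "x_max", "y_max")] <- NA_real_
    kept <- rbind(kept, orphan)
  }
  detection_stream(kept, fps = m$fps, frame_step = m$frame_step,
                   frame_size = m$frame_size)
}

#' Permanence time per treatment cell
#'
#' Estimates the cumulative time birds spent under each treatment by summing
#' the per-frame bird counts and dividing by the effective frame rate of the
#' analyzed stream.  With a noise-free detector this equals the true total
#' bird-time exactly and is invariant to down-sampling of a static scene.
#'
#' When the counts carry \code{light}/\code{temperature} annotations
#' (\code{\link{annotate_treatments}}), cells are treatment combinations;
#' otherwise they are compartments.
#'
#' @param counts a \code{count_series} (see \code{\link{frame_counts}}),
#'   optionally treatment-annotated.
#' @param fps effective frames per second of the stream the counts came from;
#'   defaults to the value recorded on \code{counts}.
#' @param flock_size number of birds, used for the per-bird normalization.
#' @param norm_days denominator of the per-bird normalization in
#'   replicate-days; defaults to the number of distinct (replicate, day)
#'   combinations observed in each cell.
#' @return a \code{permanence_result} data frame: one row per cell with
#'   \code{T_bird_seconds} (the summed counts over fps), \code{m} (total
#'   bird-observations), \code{T_bird_minutes}, \code{T_bird_hours} and
#'   \code{minutes_per_bird} (\code{T} in minutes / (flock_size x
#'   norm_days)).
#' @export
permanence_time <- function(counts, fps = attr(counts, "effective_fps"),
                            flock_size = 6, norm_days = NULL) {
  if (is.null(fps) || !is.finite(fps) || fps <= 0)
    stop("fps must be a positive number")
  df <- as.data.frame(counts)
  cell_keys <- if (all(c("light", "temperature") %in% names(df)))
    c("light", "temperature") else "compartment"
  if (nrow(df) == 0) stop("no count records")
  out <- do.call(rbind, lapply(split(df, df[cell_keys], drop = TRUE),
    function(d) {
      nd <- norm_days %||% nrow(unique(d[c("replicate", "day")]))
      cell <- d[1, cell_keys, drop = FALSE]
      cbind(cell,
            data.frame(T_bird_seconds = sum(d$count) / fps,
                       m = sum(d$count),
                       norm_days = nd))
    }))
  out$T_bird_minutes <- out$T_bird_seconds / 60
  out$T_bird_hours <- out$T_bird_seconds / 3600
  out$minutes_per_bird <- out$T_bird_minutes / (flock_size * out$norm_days)
  rownames(out) <- NULL
  structure(out[order(out[[cell_keys[length(cell_keys)]]], out[[cell_keys[1]]]), ],
            fps = fps, flock_size = flock_size,
            class = c("permanence_result", "data.frame"))
}

#' @export
print.permanence_result <- function(x, ...) {
  cat("<permanence_result> bird-time per cell (effective fps",
      attr(x, "fps"), ")\n")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Occupancy fractions per light within each temperature
#'
#' Shares of total permanence time attributed to each light color, computed
#' separately within each temperature (or over compartments when the result
#' is unannotated).  Fractions sum to 1 wherever defined; a temperature whose
#' totals are all zero is flagged with \code{NA} fractions.
#'
#' @param result a \code{permanence_result} (see
#'   \code{\link{permanence_time}}).
#' @return the result with a \code{fraction} column appended.
#' @export
occupancy_fractions <- function(result) {
  df <- as.data.frame(result)
  grp <- if ("temperature" %in% names(df)) df$temperature
         else rep("all", nrow(df))
  df$fraction <- ave(df$T_bird_seconds, grp, FUN = function(v) {
    tot <- sum(v)
    if (tot <= 0) rep(NA_real_, length(v)) else v / tot
  })
  if (anyNA(df$fraction))
    warning("occupancy fraction undefined for group(s) with zero total time",
            call. = FALSE)
  structure(df, fps = attr(result, "fps"),
            flock_size = attr(result, "flock_size"),
            class = class(result))
}

#' Per-unit permanence values for treatment comparison
#'
#' Splits permanence time into one value per statistical unit (replicate x
#' day within each treatment cell), the replication level used by the ANOVA
#' and Tukey comparisons.
#'
#' @param counts a treatment-annotated \code{count_series}.
#' @param fps effective frames per second.
#' @return data frame with \code{light}, \code{temperature},
#'   \code{replicate}, \code{day} and \code{T_bird_seconds}.
#' @export
permanence_units <- function(counts, fps = attr(counts, "effective_fps")) {
  df <- as.data.frame(counts)
  if (!all(c("light", "temperature") %in% names(df)))
    stop("counts must be treatment-annotated (see annotate_treatments)")
  out <- aggregate(list(m = df$count),
                   df[c("light", "temperature", "replicate", "day")], sum)
  out$T_bird_seconds <- out$m / fps
  out[order(out$temperature, out$light, out$replicate, out$day), ]
}
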