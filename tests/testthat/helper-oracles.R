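# Independent oracles and fixture builders shared across the suite.
# Each oracle is written as plainly as possible (explicit loops, no shared
# code with the implementation under test).

# Directed max-min distance by exhaustive double loop.
brute_directed <- function(a, b) {
  worst <- 0
  for (i in seq_len(nrow(a))) {
    nearest <- Inf
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
      if (d < nearest) nearest <- d
    }
    if (nearest > worst) worst <- nearest
  }
  worst
}

brute_symmetric_hausdorff <- function(a, b) {
  max(brute_directed(a, b), brute_directed(b, a))
}

# One-way sums of squares from first principles.
brute_anova_f <- function(groups) {
  grand <- mean(unlist(groups))
  ss_between <- 0; ss_within <- 0; n_tot <- 0
  for (g in groups) {
    ss_between <- ss_between + length(g) * (mean(g) - grand)^2
    ss_within <- ss_within + sum((g - mean(g))^2)
    n_tot <- n_tot + length(g)
  }
  df1 <- length(groups) - 1
  df2 <- n_tot - length(groups)
  (ss_between / df1) / (ss_within / df2)
}

# Two-way (balanced) sums of squares from cell/margin means, by loops.
brute_twoway_ss <- function(d) {
  grand <- mean(d$value)
  ss <- c(light = 0, temperature = 0, interaction = 0, residual = 0,
          total = sum((d$value - grand)^2))
  for (l in unique(d$light)) {
    sel <- d$light == l
    ss["light"] <- ss["light"] + sum(sel) * (mean(d$value[sel]) - grand)^2
  }
  for (t in unique(d$temperature)) {
    sel <- d$temperature == t
    ss["temperature"] <- ss["temperature"] +
      sum(sel) * (mean(d$value[sel]) - grand)^2
  }
  for (l in unique(d$light)) for (t in unique(d$temperature)) {
    sel <- d$light == l & d$temperature == t
    cell <- mean(d$value[sel])
    ml <- mean(d$value[d$light == l]); mt <- mean(d$value[d$temperature == t])
    ss["interaction"] <- ss["interaction"] +
      sum(sel) * (cell - ml - mt + grand)^2
    ss["residual"] <- ss["residual"] + sum((d$value[sel] - cell)^2)
  }
  ss
}

# Average precision by explicit PR enumeration: given ranked TP flags and the
# number of ground-truth boxes, walk every prefix of the ranking and
# integrate recall increments against the best precision at or beyond each
# cut (all-point interpolation), all with loops.
brute_ap_from_flags <- function(tp_flags, n_truth) {
  n <- length(tp_flags)
  if (n == 0) return(0)
  prec <- numeric(n); rec <- numeric(n); tp <- 0
  for (k in 1:n) {
    if (tp_flags[k]) tp <- tp + 1
    prec[k] <- tp / k
    rec[k] <- tp / n_truth
  }
  ap <- 0; prev_rec <- 0
  for (k in 1:n) {
    if (rec[k] > prev_rec) {
      best <- 0
      for (j in k:n) if (prec[j] > best) best <- prec[j]
      ap <- ap + (rec[k] - prev_rec) * best
      prev_rec <- rec[k]
    }
  }
  ap
}

# Greedy score-ordered matching, re-derived independently (simple loops) to
# turn a box instance into ranked TP flags for the oracle above.
brute_match_flags <- function(predictions, truth, iou_threshold) {
  iou1 <- function(p, g) {
    ix <- min(p$x_max, g$x_max) - max(p$x_min, g$x_min)
    iy <- min(p$y_max, g$y_max) - max(p$y_min, g$y_min)
    if (ix <= 0 || iy <= 0) return(0)
    inter <- ix * iy
    a1 <- (p$x_max - p$x_min) * (p$y_max - p$y_min)
    a2 <- (g$x_max - g$x_min) * (g$y_max - g$y_min)
    inter / (a1 + a2 - inter)
  }
  preds <- predictions[order(-predictions$score), , drop = FALSE]
  used <- rep(FALSE, nrow(truth))
  flags <- logical(nrow(preds))
  for (i in seq_len(nrow(preds))) {
    best <- 0; best_j <- 0
    for (j in seq_len(nrow(truth))) {
      if (used[j] || truth$image[j] != preds$image[i]) next
      v <- iou1(preds[i, ], truth[j, ])
      if (v > best) { best <- v; best_j <- j }
    }
    if (best_j > 0 && best >= iou_threshold) {
      flags[i] <- TRUE; used[best_j] <- TRUE
    }
  }
  flags
}

# Random point sets / box helpers ----------------------------------------

random_centroids <- function(n, width = 702, height = 480) {
  cbind(runif(n, 0, width), runif(n, 0, height))
}

boxes_from_points <- function(pts, half_w = 30, half_h = 25) {
  data.frame(x_min = pts[, 1] - half_w, y_min = pts[, 2] - half_h,
             x_max = pts[, 1] + half_w, y_max = pts[, 2] + half_h)
}

# A minimal hand-built stream: `positions` is a list (indexed by frame) of
# centroid matrices for one compartment.
stream_from_positions <- function(positions, compartment = "A", fps = 15,
                                  experiment_id = 1, session = "morning",
                                  frame_offset = 0, replicate = 1, day = 1) {
  rows <- lapply(seq_along(positions), function(i) {
    pts <- positions[[i]]
    fi <- frame_offset + i - 1
    if (is.null(pts) || nrow(pts) == 0)
      return(data.frame(experiment_id = experiment_id, replicate = replicate,
                        day = day, session = session,
                        compartment = compartment, frame_index = fi,
                        timestamp_s = fi / fps, x_min = NA_real_,
                        y_min = NA_real_, x_max = NA_real_, y_max = NA_real_))
    b <- boxes_from_points(pts, half_w = 5, half_h = 5)
    data.frame(experiment_id = experiment_id, replicate = replicate,
               day = day, session = session, compartment = compartment,
               frame_index = fi, timestamp_s = fi / fps,
               x_min = b$x_min, y_min = b$y_min, x_max = b$x_max,
               y_max = b$y_max)
  })
  detection_stream(do.call(rbind, rows), fps = fps)
}
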