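#' Simulator configuration
#'
#' Parameters of the agent-based chamber simulator: a flock of hens moving
#' independently among the compartments of the chamber, observed through
#' per-compartment overhead detectors with configurable noise.
#'
#' Movement model: each bird is an independent continuous-time Markov chain
#' on the compartment adjacency graph.  The transition rate from compartment
#' c to an adjacent compartment c' is proportional to the preference weight
#' of c', which satisfies detailed balance on any symmetric adjacency graph
#' and makes the long-run occupancy of each compartment exactly proportional
#' to its preference weight -- the analytically computable ground truth that
#' parameter-recovery tests rely on
#' (\code{\link{stationary_occupancy}}).  The common rate factor is
#' calibrated so that, at stationarity, a bird changes compartment
#' \code{switch_rate} times per hour on average.
#'
#' Within a compartment a bird's centroid performs a reflected Gaussian
#' random walk with per-frame step standard deviation \code{within_step_px *
#' activity_scale}; a bird entering through a known door starts at that door
#' edge.  Detections are the true centroids plus isotropic Gaussian jitter,
#' dropped independently with probability \code{miss_prob}; at a
#' compartment-crossing frame, the bird is additionally detected in the
#' compartment it just left with probability \code{double_prob} (the doorway
#' double-detection artifact).  Boxes are fixed-size rectangles centered on
#' the detected centroid.
#'
#' @param flock_size number of hens (default 6).
#' @param preference_weights positive named weights for compartments A, B, C;
#'   long-run occupancy is proportional to them.
#' @param switch_rate expected compartment changes per bird-hour.
#' @param within_step_px per-frame movement scale in pixels.
#' @param activity_scale multiplier on \code{within_step_px} (temperature
#'   scenarios lower it under heat stress).
#' @param miss_prob per-bird per-frame probability of a missed detection.
#' @param double_prob per-crossing probability of a doorway double detection.
#' @param jitter_px standard deviation of centroid detection noise in pixels.
#' @param fps frame rate of the emitted stream (15 by default, the analyzed
#'   rate).
#' @param duration_s simulated duration in seconds.
#' @param adjacency symmetric 0/1 compartment adjacency matrix (fully
#'   connected by default -- every compartment pair shares a door).
#' @param doors door-edge geometry (see \code{\link{default_doors}}).
#' @param box_size \code{c(width, height)} of emitted boxes in pixels.
#' @param frame_size camera frame size in pixels.
#' @param experiment_id,replicate,day,session metadata stamped on the emitted
#'   stream.
#' @param start starting compartment for every bird, or \code{NULL} (default)
#'   to draw each bird's start from the stationary distribution.
#' @param seed mandatory RNG seed: identical seeds give bit-identical output.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(flock_size = 6L,
                       preference_weights = c(A = 1, B = 1, C = 1),
                       switch_rate = 60,
                       within_step_px = 6,
                       activity_scale = 1,
                       miss_prob = 0,
                       double_prob = 0,
                       jitter_px = 0,
                       fps = 15,
                       duration_s = 600,
                       adjacency = NULL,
                       doors = default_doors(),
                       box_size = c(60, 50),
                       frame_size = default_frame_size(),
                       experiment_id = 1L, replicate = 1L, day = 1L,
                       session = "morning",
                       start = NULL,
                       seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  comps <- names(preference_weights)
  if (is.null(comps)) {
    comps <- LETTERS[seq_along(preference_weights)]
    names(preference_weights) <- comps
  }
  if (any(preference_weights <= 0)) stop("preference weights must be > 0")
  if (any(c(miss_prob, double_prob) < 0) || any(c(miss_prob, double_prob) > 1))
    stop("probabilities must lie in [0, 1]")
  if (fps <= 0) stop("fps must be > 0")
  if (is.null(adjacency)) {
    n <- length(comps)
    adjacency <- matrix(1, n, n, dimnames = list(comps, comps)) - diag(n)
  }
  if (!isSymmetric(unname(adjacency)))
    stop("adjacency must be symmetric (doors open both ways)")
  if (!is_connected(adjacency))
    stop("adjacency graph is disconnected: birds could never reach some compartments")
  structure(list(flock_size = as.integer(flock_size),
                 preference_weights = preference_weights,
                 switch_rate = switch_rate, within_step_px = within_step_px,
                 activity_scale = activity_scale, miss_prob = miss_prob,
                 double_prob = double_prob, jitter_px = jitter_px, fps = fps,
                 duration_s = duration_s, adjacency = adjacency,
                 doors = doors, box_size = box_size, frame_size = frame_size,
                 experiment_id = experiment_id, replicate = replicate,
                 day = day, session = session, start = start, seed = seed),
            class = "sim_config")
}

is_connected <- function(adj) {
  n <- nrow(adj)
  seen <- c(1L)
  repeat {
    nxt <- unique(c(seen, which(colSums(adj[seen, , drop = FALSE] > 0) > 0)))
    if (length(nxt) == length(seen)) break
    seen <- nxt
  }
  length(seen) == n
}

# Generator matrix at unit rate factor: Q[c, c'] = w[c'] * adj[c, c']
unit_generator <- function(config) {
  w <- config$preference_weights
  q <- sweep(config$adjacency, 2, w, `*`)
  diag(q) <- -rowSums(q)
  dimnames(q) <- list(names(w), names(w))
  q
}

#' Exact long-run occupancy of the simulated chamber
#'
#' Solves the global balance equations \eqn{\pi Q = 0}, \eqn{\sum \pi = 1} of
#' the configured movement chain by linear algebra -- the independent oracle
#' that Monte-Carlo occupancy estimates are checked against.  For the
#' detailed-balance movement model this equals the normalized preference
#' weights, but the solver makes no use of that fact.
#'
#' @param config a \code{\link{sim_config}}.
#' @return named numeric vector of stationary occupancy fractions, summing
#'   to 1.
#' @export
stationary_occupancy <- function(config) {
  q <- unit_generator(config)
  n <- nrow(q)
  a <- t(q)
  a[n, ] <- 1
  pi_ <- solve(a, c(rep(0, n - 1), 1))
  setNames(pmax(pi_, 0) / sum(pmax(pi_, 0)), rownames(q))
}

reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  r <- (x - lo) %% (2 * span)
  lo + ifelse(r > span, 2 * span - r, r)
}

door_entry_point <- function(comp, from, doors, lo, hi) {
  # entry coordinates (x, y) when arriving in `comp` from `from`; NULL if the
  # geometry declares no door between the two
  for (r in seq_len(nrow(doors))) {
    if (doors$comp_1[r] == comp && doors$comp_2[r] == from)
      edge <- doors$edge_1[r]
    else if (doors$comp_2[r] == comp && doors$comp_1[r] == from)
      edge <- doors$edge_2[r]
    else next
    return(switch(edge,
                  left   = c(lo[1], mean(c(lo[2], hi[2]))),
                  right  = c(hi[1], mean(c(lo[2], hi[2]))),
                  top    = c(mean(c(lo[1], hi[1])), lo[2]),
                  bottom = c(mean(c(lo[1], hi[1])), hi[2])))
  }
  NULL
}

#' Simulate the chamber
#'
#' Runs the movement and detection model of \code{\link{sim_config}} and
#' returns both the ground truth and the noisy detection stream in the
#' canonical CSV dialect.  Per-frame true counts always sum to the flock
#' size; with all noise off, the detection stream reproduces the truth
#' exactly (one box per bird per frame, centered on the true centroid).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{truth} (data frame \code{frame_index, bird_id,
#'   compartment, x, y}), \code{stream} (a \code{\link{detection_stream}})
#'   and \code{config}.
#' @export
simulate_epc <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  comps <- names(config$preference_weights)
  w <- config$preference_weights
  n_frames <- as.integer(round(config$duration_s * config$fps))
  if (n_frames < 1) stop("duration too short for a single frame")
  frame_t <- (seq_len(n_frames) - 1) / config$fps

  qunit <- unit_generator(config)
  pi_ <- stationary_occupancy(config)
  # calibrate the rate factor: stationary mean exit rate == switch_rate / h
  mean_exit_unit <- sum(pi_ * -diag(qunit))
  r_per_s <- if (config$switch_rate > 0 && mean_exit_unit > 0)
    (config$switch_rate / mean_exit_unit) / 3600 else 0
  exit_rate <- -diag(qunit) * r_per_s          # per second, per compartment

  lo <- config$box_size / 2
  hi <- config$frame_size - config$box_size / 2
  step_sd <- config$within_step_px * config$activity_scale

  truth <- vector("list", config$flock_size)
  for (b in seq_len(config$flock_size)) {
    # sojourn sequence of the continuous-time chain
    state <- if (is.null(config$start)) sample(seq_along(comps), 1, prob = pi_)
             else match(config$start, comps)
    states <- integer(0); starts <- numeric(0)
    t_now <- 0
    repeat {
      states <- c(states, state); starts <- c(starts, t_now)
      if (exit_rate[state] <= 0) break
      t_now <- t_now + rexp(1, exit_rate[state])
      if (t_now >= config$duration_s) break
      nbr <- which(config$adjacency[state, ] > 0)
      state <- if (length(nbr) == 1) nbr else
        sample(nbr, 1, prob = w[nbr])
    }
    comp_at_frame <- states[findInterval(frame_t, starts)]
    # positions: reflected random walk, restarted per sojourn
    x <- numeric(n_frames); y <- numeric(n_frames)
    runs <- rle(comp_at_frame)
    pos <- cumsum(c(0, runs$lengths))
    for (k in seq_along(runs$lengths)) {
      idx <- (pos[k] + 1):pos[k + 1]
      entry <- NULL
      if (k > 1)
        entry <- door_entry_point(comps[runs$values[k]],
                                  comps[runs$values[k - 1]],
                                  config$doors, lo, hi)
      x0 <- if (is.null(entry)) runif(1, lo[1], hi[1]) else entry[1]
      y0 <- if (is.null(entry)) runif(1, lo[2], hi[2]) else entry[2]
      nk <- length(idx)
      x[idx] <- reflect_into(x0 + cumsum(c(0, rnorm(nk - 1, 0, step_sd))),
                             lo[1], hi[1])
      y[idx] <- reflect_into(y0 + cumsum(c(0, rnorm(nk - 1, 0, step_sd))),
                             lo[2], hi[2])
    }
    truth[[b]] <- data.frame(frame_index = seq_len(n_frames) - 1L,
                             bird_id = b,
                             compartment = comps[comp_at_frame],
                             x = x, y = y)
  }
  truth <- do.call(rbind, truth)

  # --- detection model ---------------------------------------------------
  det <- truth
  # doorway double detections at crossing frames
  ord <- order(det$bird_id, det$frame_index)
  det <- det[ord, ]
  crossing <- c(FALSE, det$compartment[-1] != det$compartment[-nrow(det)] &
                       det$bird_id[-1] == det$bird_id[-nrow(det)])
  dup_idx <- which(crossing & runif(nrow(det)) < config$double_prob)
  if (length(dup_idx)) {
    dup <- det[dup_idx, ]
    prev_comp <- det$compartment[dup_idx - 1]
    for (i in seq_along(dup_idx)) {
      entry <- door_entry_point(prev_comp[i], dup$compartment[i],
                                config$doors, lo, hi)
      if (!is.null(entry)) { dup$x[i] <- entry[1]; dup$y[i] <- entry[2] }
    }
    dup$compartment <- prev_comp
    det <- rbind(det, dup)
  }
  # misses and jitter
  det <- det[runif(nrow(det)) >= config$miss_prob, , drop = FALSE]
  if (config$jitter_px > 0) {
    det$x <- det$x + rnorm(nrow(det), 0, config$jitter_px)
    det$y <- det$y + rnorm(nrow(det), 0, config$jitter_px)
  }
  det$x <- pmin(pmax(det$x, lo[1]), hi[1])
  det$y <- pmin(pmax(det$y, lo[2]), hi[2])

  stream_df <- data.frame(experiment_id = config$experiment_id,
                          replicate = config$replicate, day = config$day,
                          session = config$session,
                          compartment = det$compartment,
                          frame_index = det$frame_index,
                          timestamp_s = det$frame_index / config$fps,
                          x_min = det$x - config$box_size[1] / 2,
                          y_min = det$y - config$box_size[2] / 2,
                          x_max = det$x + config$box_size[1] / 2,
                          y_max = det$y + config$box_size[2] / 2)
  # explicit empty-frame records for every (compartment, frame) with no box
  seen <- table(factor(det$compartment, levels = comps),
                factor(det$frame_index, levels = seq_len(n_frames) - 1L))
  zero <- which(seen == 0, arr.ind = TRUE)
  if (nrow(zero)) {
    fi <- as.integer(colnames(seen)[zero[, 2]])
    stream_df <- rbind(stream_df,
      data.frame(experiment_id = config$experiment_id,
                 replicate = config$replicate, day = config$day,
                 session = config$session,
                 compartment = rownames(seen)[zero[, 1]],
                 frame_index = fi, timestamp_s = fi / config$fps,
                 x_min = NA_real_, y_min = NA_real_,
                 x_max = NA_real_, y_max = NA_real_))
  }
  truth <- truth[order(truth$frame_index, truth$bird_id), ]
  rownames(truth) <- NULL
  list(truth = truth,
       stream = detection_stream(stream_df, fps = config$fps,
                                 frame_size = config$frame_size),
       config = config)
}

#' Aligned count sequences for validation-protocol tests
#'
#' Builds a fixture mimicking the manual count-validation protocol: per-frame
#' true bird counts with a prescribed number of over-count-by-one detector
#' errors, so the downstream confusion-matrix arithmetic can be exercised
#' with a known answer.
#'
#' @param n_frames number of validated frames.
#' @param n_overcounts how many frames get a predicted count of true + 1.
#' @param flock_size maximum simultaneous birds per frame (default 6).
#' @param seed RNG seed.
#' @return list with integer vectors \code{true} and \code{predicted} of
#'   length \code{n_frames}.
#' @export
make_validation_fixture <- function(n_frames, n_overcounts,
                                    flock_size = 6L, seed = 1L) {
  if (n_overcounts > n_frames)
    stop("cannot place more errors than frames")
  set.seed(seed)
  true <- sample(0:flock_size, n_frames, replace = TRUE)
  predicted <- true
  err <- sample.int(n_frames, n_overcounts)
  predicted[err] <- predicted[err] + 1L
  list(true = as.integer(true), predicted = as.integer(predicted))
}

#' Scenario presets for the three thermal environments
#'
#' Qualitative presets used for pipeline demonstrations, mirroring the
#' observed behavioral pattern: in the cold, birds crowd under white light
#' and move normally; at thermoneutrality the preference is milder; under
#' heat stress the light preference flattens toward uniform and activity
#' drops.  These are demonstration settings, not measurements of real hens.
#'
#' @param scenario \code{"cold"}, \code{"thermoneutral"} or \code{"hot"}.
#' @param light_map named character vector mapping compartments to lights
#'   (defaults to experiment 1 of the design: A white, B green, C red).
#' @param ... overrides passed on to \code{\link{sim_config}} (a \code{seed}
#'   must be supplied).
#' @return a \code{\link{sim_config}}.
#' @export
epc_scenario <- function(scenario = c("thermoneutral", "cold", "hot"),
                         light_map = c(A = "white", B = "green", C = "red"),
                         ...) {
  scenario <- match.arg(scenario)
  light_pref <- switch(scenario,
                       cold         = c(white = 0.60, red = 0.25, green = 0.15),
                       thermoneutral = c(white = 0.45, red = 0.35, green = 0.20),
                       hot          = c(white = 0.35, red = 0.33, green = 0.32))
  act <- switch(scenario, cold = 1, thermoneutral = 1, hot = 0.6)
  weights <- setNames(unname(light_pref[light_map]), names(light_map))
  sim_config(preference_weights = weights, activity_scale = act, ...)
}
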