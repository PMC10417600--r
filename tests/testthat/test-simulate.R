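quick_cfg <- function(...) {
  args <- list(...)
  defaults <- list(flock_size = 3L, duration_s = 60, fps = 15, seed = 9,
                   preference_weights = c(A = 1, B = 1, C = 1))
  do.call(sim_config, utils::modifyList(defaults, args))
}

test_that("identical seeds reproduce the simulation bit for bit", {
  a <- simulate_epc(quick_cfg(seed = 42, jitter_px = 2, miss_prob = 0.05,
                              double_prob = 0.3))
  b <- simulate_epc(quick_cfg(seed = 42, jitter_px = 2, miss_prob = 0.05,
                              double_prob = 0.3))
  expect_identical(a$truth, b$truth)
  expect_identical(as.data.frame(a$stream), as.data.frame(b$stream))
  c_ <- simulate_epc(quick_cfg(seed = 43))
  expect_false(identical(a$truth, c_$truth))
})

test_that("per-frame true counts always sum to the flock size", {
  sim <- simulate_epc(quick_cfg(flock_size = 5L, seed = 3,
                                preference_weights = c(A = 3, B = 2, C = 1)))
  per_frame <- table(sim$truth$frame_index)
  expect_true(all(per_frame == 5))
  # each bird sits in exactly one compartment per frame
  expect_false(any(duplicated(sim$truth[c("frame_index", "bird_id")])))
})

test_that("with no switching, birds stay where they started", {
  sim <- simulate_epc(quick_cfg(switch_rate = 0, start = "A", seed = 4))
  expect_true(all(sim$truth$compartment == "A"))
  pt <- permanence_time(frame_counts(sim$stream), flock_size = 3)
  expect_equal(pt$T_bird_seconds[pt$compartment == "A"], 3 * 60)
  expect_equal(sum(pt$T_bird_seconds[pt$compartment != "A"]), 0)
})

test_that("stationary occupancy solves the chain's balance equations", {
  expect_equal(unname(stationary_occupancy(quick_cfg(seed = 1))),
               rep(1 / 3, 3))
  # two compartments, rate A->B twice B->A -> fractions (1/3, 2/3)
  cfg2 <- sim_config(preference_weights = c(A = 1, B = 2), seed = 1,
                     adjacency = matrix(c(0, 1, 1, 0), 2,
                                        dimnames = list(c("A", "B"),
                                                        c("A", "B"))),
                     doors = data.frame(comp_1 = "A", edge_1 = "right",
                                        comp_2 = "B", edge_2 = "left"))
  expect_equal(unname(stationary_occupancy(cfg2)), c(1, 2) / 3)
  # for the detailed-balance movement model, occupancy tracks the weights
  w <- c(A = 0.5, B = 0.3, C = 0.2)
  expect_equal(stationary_occupancy(quick_cfg(preference_weights = w)),
               w / sum(w))
})

test_that("empirical occupancy approaches the analytic stationary law", {
  w <- c(A = 2, B = 1, C = 1)
  cfg <- quick_cfg(preference_weights = w, flock_size = 6L,
                   switch_rate = 360, duration_s = 600, seed = 12)
  sim <- simulate_epc(cfg)
  emp <- prop.table(table(sim$truth$compartment))
  # 1 bird-hour of data: three Monte-Carlo standard errors is about 0.09
  expect_lt(max(abs(as.numeric(emp[names(w)]) -
                    unname(stationary_occupancy(cfg)))), 0.09)
})

test_that("disconnected adjacency and bad weights are rejected", {
  adj <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  adj["A", "B"] <- adj["B", "A"] <- 1   # C unreachable
  expect_error(quick_cfg(adjacency = adj), "disconnected")
  expect_error(quick_cfg(preference_weights = c(A = 1, B = 0, C = 1)),
               "> 0")
  expect_error(sim_config(flock_size = 3), "seed")
})

test_that("noise-free streams reproduce ground truth exactly through the pipeline", {
  cfg <- quick_cfg(flock_size = 4L, seed = 6,
                   preference_weights = c(A = 2, B = 1, C = 1),
                   switch_rate = 120)
  sim <- simulate_epc(cfg)
  pt <- permanence_time(frame_counts(sim$stream), flock_size = 4)
  # conservation: total bird-time equals flock x duration
  expect_equal(sum(pt$T_bird_seconds), 4 * 60)
  # per compartment it equals the truth's bird-frames / fps
  truth_t <- table(sim$truth$compartment) / 15
  for (comp in names(truth_t))
    expect_equal(pt$T_bird_seconds[pt$compartment == comp],
                 as.numeric(truth_t[comp]))
})

test_that("doorway double detections inflate scene counts at the configured rate", {
  cfg <- quick_cfg(flock_size = 6L, duration_s = 400, switch_rate = 240,
                   double_prob = 1, seed = 8)
  sim <- simulate_epc(cfg)
  counts <- frame_counts(sim$stream)
  per_scene <- tapply(counts$count, counts$frame_index, sum)
  crossings <- sum(tapply(sim$truth$compartment, sim$truth$bird_id,
                          function(x) sum(x[-1] != x[-length(x)])))
  # with double_prob = 1 every crossing frame over-counts by exactly one
  expect_equal(sum(per_scene - 6), crossings)
  expect_true(all(per_scene - 6 >= 0))
})

test_that("doubling the activity scale doubles single-bird unrest", {
  mk <- function(scale, seed) {
    cfg <- sim_config(flock_size = 1L, preference_weights = c(A = 1),
                      adjacency = matrix(0, 1, 1, dimnames = list("A", "A")),
                      switch_rate = 0, within_step_px = 3,
                      activity_scale = scale, duration_s = 400, fps = 15,
                      seed = seed)
    mean(unrest_series(simulate_epc(cfg)$stream)$value)
  }
  set.seed(1)
  lo <- mean(vapply(1:4, function(s) mk(1, s), 0))
  hi <- mean(vapply(1:4, function(s) mk(2, s + 100), 0))
  expect_equal(hi / lo, 2, tolerance = 0.1)
})

test_that("validation fixtures carry exactly the requested error pattern", {
  fx <- make_validation_fixture(100, 7, seed = 2)
  expect_equal(sum(fx$predicted != fx$true), 7)
  expect_true(all((fx$predicted - fx$true) %in% c(0L, 1L)))
  fx0 <- make_validation_fixture(50, 0)
  expect_equal(count_accuracy(count_confusion(fx0$true, fx0$predicted)), 100)
  fx_all <- make_validation_fixture(50, 50)
  m <- count_confusion(fx_all$true, fx_all$predicted)
  expect_equal(count_accuracy(m), 0)
  expect_equal(overcount_rate(m), 100)
  expect_error(make_validation_fixture(10, 11), "more errors")
})

test_that("scenario presets map light preferences onto compartments", {
  cfg <- epc_scenario("cold", seed = 1)
  expect_gt(cfg$preference_weights[["A"]], cfg$preference_weights[["C"]])
  expect_gt(cfg$preference_weights[["C"]], cfg$preference_weights[["B"]])
  hot <- epc_scenario("hot", seed = 1)
  spread <- function(w) diff(range(w / sum(w)))
  expect_lt(spread(hot$preference_weights), spread(cfg$preference_weights))
  expect_lt(hot$activity_scale, 1)
})
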