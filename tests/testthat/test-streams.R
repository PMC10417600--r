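csv_line <- function(...) paste(..., sep = ",")

write_fixture_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(c(paste(c("experiment_id", "replicate", "day", "session",
                       "compartment", "frame_index", "timestamp_s",
                       "x_min", "y_min", "x_max", "y_max"), collapse = ","),
               lines), f)
  f
}

test_that("a single box record round-trips through the CSV reader", {
  f <- write_fixture_csv(csv_line(1, 1, 1, "morning", "A", 0, 0,
                                  10, 10, 50, 50))
  s <- read_detection_csv(f)
  expect_s3_class(s, "detection_stream")
  expect_equal(nrow(s), 1)
  expect_equal(s$x_min, 10)
  expect_equal(s$x_max, 50)
  expect_equal(s$compartment, "A")
})

test_that("a header-only file yields an empty stream without error", {
  f <- write_fixture_csv(character(0))
  s <- read_detection_csv(f)
  expect_equal(nrow(s), 0)
  expect_s3_class(s, "detection_stream")
})

test_that("empty-frame records are preserved as explicit zero-count rows", {
  f <- write_fixture_csv(c(csv_line(1, 1, 1, "morning", "A", 0, 0,
                                    10, 10, 50, 50),
                           csv_line(1, 1, 1, "morning", "A", 1, "", "", "", "", "")))
  s <- read_detection_csv(f)
  expect_equal(nrow(s), 2)
  counts <- frame_counts(s)
  expect_equal(counts$count, c(1L, 0L))
})

test_that("malformed rows are rejected with the offending line number", {
  f <- write_fixture_csv(c(csv_line(1, 1, 1, "morning", "A", 0, 0,
                                    10, 10, 50, 50),
                           "1,1,1,morning,A,1"))
  expect_error(read_detection_csv(f), "line 3")
  f2 <- write_fixture_csv(csv_line(1, 1, 1, "morning", "A", 0, 0,
                                   "oops", 10, 50, 50))
  expect_error(read_detection_csv(f2), "line 2")
  f3 <- write_fixture_csv(csv_line(1, 1, 1, "morning", "A", 0, 0,
                                   10, "", 50, 50))
  expect_error(read_detection_csv(f3), "partially empty")
})

test_that("boxes violating the geometry invariant are dropped with a warning", {
  f <- write_fixture_csv(c(csv_line(1, 1, 1, "morning", "A", 0, 0,
                                    10, 10, 50, 50),
                           csv_line(1, 1, 1, "morning", "A", 1, "",
                                    60, 10, 50, 50)))  # x_min >= x_max
  expect_warning(s <- read_detection_csv(f), "1 box record")
  # the emptied frame survives as an explicit empty record
  expect_equal(frame_counts(s)$count, c(1L, 0L))
})

test_that("write-then-read reproduces a canonical file byte for byte", {
  set.seed(41)
  for (rep in 1:5) {
    positions <- lapply(1:8, function(i) {
      n <- sample(0:4, 1)
      if (n == 0) NULL else random_centroids(n, 600, 400) + 20
    })
    s <- stream_from_positions(positions)
    f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
    write_detection_csv(s, f1)
    write_detection_csv(read_detection_csv(f1, fps = 15), f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
    s2 <- read_detection_csv(f1, fps = 15)
    expect_equal(as.data.frame(s2), as.data.frame(s))
  }
})

test_that("centroid is the box midpoint", {
  expect_equal(centroid(data.frame(x_min = 0, y_min = 0,
                                   x_max = 10, y_max = 20)),
               data.frame(x = 5, y = 10))
  set.seed(11)
  a <- runif(20, 0, 300); b <- runif(20, 0, 200)
  w <- runif(20, 1, 50); h <- runif(20, 1, 50)
  cc <- centroid(data.frame(x_min = a, y_min = b, x_max = a + w, y_max = b + h))
  expect_equal(cc$x, a + w / 2)
  expect_equal(cc$y, b + h / 2)
})

test_that("degenerate near-zero-area boxes fail the box invariant", {
  expect_false(valid_boxes(data.frame(x_min = 0, y_min = 0,
                                      x_max = 1e-6, y_max = 1e-6),
                           min_area = 1e-6))
  expect_true(valid_boxes(data.frame(x_min = 0, y_min = 0,
                                     x_max = 10, y_max = 10)))
})

test_that("downsample keeps indices congruent to zero and tracks effective fps", {
  s <- stream_from_positions(lapply(1:30, function(i) cbind(10 * i, 50)),
                             fps = 30)
  d2 <- downsample(s, 2)
  expect_equal(sort(unique(d2$frame_index)), seq(0, 28, by = 2))
  expect_equal(effective_fps(d2), 15)
  expect_equal(as.data.frame(downsample(s, 1)), as.data.frame(s))
  d30 <- downsample(s, 30)
  expect_equal(nrow(d30), 1)   # one frame per second of footage
  expect_error(downsample(s, 0), "positive integer")
})

test_that("down-sampling composes multiplicatively", {
  s <- stream_from_positions(lapply(1:60, function(i) cbind(5 * i, 50)),
                             fps = 30)
  ab <- downsample(downsample(s, 2), 3)
  once <- downsample(s, 6)
  expect_equal(as.data.frame(ab), as.data.frame(once))
  expect_equal(effective_fps(ab), effective_fps(once))
})

test_that("window selection keeps exactly the in-window frames, half-open", {
  # one frame per minute over 24 h
  fps <- 1 / 60
  idx <- 0:(24 * 60 - 1)
  df <- data.frame(experiment_id = 1, replicate = 1, day = 1,
                   session = "all", compartment = "A", frame_index = idx,
                   timestamp_s = idx * 60,
                   x_min = 10, y_min = 10, x_max = 40, y_max = 40)
  s <- detection_stream(df, fps = fps)
  w <- select_windows(s, observation_windows())
  expect_equal(nrow(w), 4 * 60)          # two 2-h windows of minutes
  expect_setequal(unique(w$session), c("morning", "afternoon"))
  # frame exactly at a window end is excluded
  expect_false((11 * 3600 + 30 * 60) %in% w$timestamp_s)
  expect_true((9 * 3600 + 30 * 60) %in% w$timestamp_s)
  # relative frame order preserved within each window, nothing fabricated
  for (sess in unique(w$session))
    expect_true(!is.unsorted(w$timestamp_s[w$session == sess]))
  expect_true(all(w$timestamp_s %in% df$timestamp_s))
})

test_that("an empty window list empties the stream; overlap is an error", {
  s <- stream_from_positions(lapply(1:5, function(i) cbind(10, 10)))
  w0 <- observation_windows()[0, ]
  expect_equal(nrow(select_windows(s, w0)), 0)
  overlapping <- data.frame(session = c("a", "b"),
                            start_s = c(0, 1800), end_s = c(3600, 5400))
  expect_error(select_windows(s, overlapping), "overlap")
})

test_that("timestamps are derived from frame index and fps when absent", {
  df <- data.frame(experiment_id = 1, replicate = 1, day = 1,
                   session = "morning", compartment = "A", frame_index = 0:4,
                   timestamp_s = NA_real_,
                   x_min = 1, y_min = 1, x_max = 9, y_max = 9)
  s <- detection_stream(df, fps = 10)
  expect_equal(s$timestamp_s, (0:4) / 10)
})
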