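test_that("gaze table round-trips exactly and infers rate from timestamps", {
  set.seed(11)
  n <- 30
  df <- data.frame(t = (0:(n - 1)) * 1000 / 60,
                   left_x = runif(n, 0, 1919), left_y = runif(n, 0, 1079),
                   right_x = runif(n, 0, 1919), right_y = runif(n, 0, 1079))
  g <- gaze_stream(df)
  expect_equal(g$nominal_rate_hz, 60, tolerance = 1e-9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gaze_table(g, path)
  g2 <- read_gaze_table(path)
  expect_identical(g2$samples$t, g$samples$t)
  expect_identical(g2$samples$left_x, g$samples$left_x)
  expect_identical(g2$samples$right_y, g$samples$right_y)
  expect_identical(g2$samples$valid_left, g$samples$valid_left)
})

test_that("gaze reader maps columns through a schema and reports schema errors", {
  df <- data.frame(time = c(0, 16, 33), lx = 1:3, ly = 1:3, rx = 1:3, ry = 1:3)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  g <- read_gaze_table(path, schema = c(t_ms = "time", left_x = "lx",
                                        left_y = "ly", right_x = "rx",
                                        right_y = "ry"))
  expect_equal(nrow(g$samples), 3L)
  expect_error(read_gaze_table(path), "schema error.*t_ms")
  expect_error(read_gaze_table(path, schema = c(bogus = "time")),
               "unknown column")
})

test_that("gaze reader rejects non-monotone time naming the offending row", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(t_ms = c(0, 16, 16), left_x = 1, left_y = 1,
                       right_x = 1, right_y = 1), path, row.names = FALSE)
  expect_error(read_gaze_table(path), "format error.*row 3")
})

test_that("gaze reader rejects tables with fewer than two rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(t_ms = 0, left_x = 1, left_y = 1,
                       right_x = 1, right_y = 1), path, row.names = FALSE)
  expect_error(read_gaze_table(path), "insufficient data")
})

test_that("samples without validity columns are valid iff inside screen bounds", {
  df <- data.frame(t = c(0, 16, 33),
                   left_x = c(100, -1, 500), left_y = c(100, -1, 500),
                   right_x = c(100, -1, 2000), right_y = c(100, -1, 500))
  g <- gaze_stream(df)
  expect_identical(g$samples$valid_left, c(TRUE, FALSE, TRUE))
  expect_identical(g$samples$valid_right, c(TRUE, FALSE, FALSE))
})

test_that("hand reader round-trips, and handles NaN by mode", {
  df <- data.frame(t_ms = c(0, 10, 20, 30, 40),
                   tool_x = c(1, 1, NaN, 1, 1), tool_y = 1, tool_z = 1,
                   cam_x = 0, cam_y = 0, cam_z = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(read_hand_table(path), "non-finite position.*row 3")
  h <- read_hand_table(path, mode = "permissive")
  expect_identical(h$samples$valid_tool, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_hand_table(h, path2)
  h2 <- read_hand_table(path2, mode = "permissive")
  expect_identical(h2$samples$tool_y, h$samples$tool_y)
  expect_identical(h2$samples$valid_tool, h$samples$valid_tool)
})

test_that("constant-position hand table parses to a valid stream", {
  df <- data.frame(t_ms = seq(0, 40, by = 10), tool_x = 5, tool_y = 5,
                   tool_z = 5, cam_x = 0, cam_y = 0, cam_z = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  h <- read_hand_table(path)
  expect_s3_class(h, "hand_stream")
  expect_equal(nrow(h$samples), 5L)
  expect_equal(h$nominal_rate_hz, 100, tolerance = 1e-9)
})

test_that("event tables round-trip through CSV, including the empty table", {
  ev <- manual_events(c("stable", "rapid"), c(0, 100), c(100, 140),
                      cx = c(10, 20), cy = c(5, 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_table(ev, path)
  back <- read_event_table(path)
  expect_equal(back$events, ev$events)
  expect_identical(back$events$duration,
                   back$events$t_end - back$events$t_start)

  empty <- manual_events(character(), numeric(), numeric(),
                         cx = numeric(), cy = numeric())
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_event_table(empty, path2)
  expect_identical(nrow(read_event_table(path2)$events), 0L)
})

test_that("metrics tables round-trip, including zero records", {
  recs <- data.frame(participant = c("a", "a"), scenario = "S1", task = 0:1,
                     FD = c(120.5, NA), FN = c(3L, 0L), SN = c(2L, 0L),
                     SSD = c(300, 210.25), SSN = c(4L, 2L), SSM = c(1L, 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_table(recs, path)
  back <- read_metrics_table(path)
  expect_equal(back, recs)

  path2 <- withr::local_tempfile(fileext = ".csv")
  write_metrics_table(recs[0, ], path2)
  expect_identical(nrow(read_metrics_table(path2)), 0L)
})

test_that("marker tables round-trip", {
  mk <- data.frame(task_index = 0:2, t_start = c(0, 10500, 21000),
                   t_end = c(10000, 20500, 31000),
                   completed = c(TRUE, TRUE, FALSE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_markers(mk, path)
  expect_equal(read_markers(path), mk)
})
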