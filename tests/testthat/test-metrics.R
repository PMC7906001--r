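seg <- function(t0, t1, idx = 0L) {
  data.frame(task_index = idx, t_start = t0, t_end = t1, completed = TRUE)
}

test_that("eye metrics follow their definitions on a hand-made sequence", {
  ev <- manual_events(c("stable", "rapid", "stable"),
                      c(0, 100, 160), c(100, 160, 300))
  m <- eye_metrics(ev, seg(0, 300))
  expect_equal(m$FD, 120)  # mean of 100 and 140
  expect_equal(m$FN, 2L)
  expect_equal(m$SN, 1L)
})

test_that("segments holding only gaps give zero counts and missing FD", {
  ev <- manual_events(c("gap", "stable"), c(0, 500), c(500, 900))
  m <- eye_metrics(ev, seg(0, 450))
  expect_equal(m$FN, 0L)
  expect_equal(m$SN, 0L)
  expect_true(is.na(m$FD))
})

test_that("alternating stand-stills and sharp moves reduce to the planted numbers", {
  # 10 x 500 ms stable + 10 x 100 ms rapid = 6000 ms
  kinds <- rep(c("stable", "rapid"), 10)
  starts <- cumsum(c(0, rep(c(500, 100), 10)))[1:20]
  ev <- manual_events(kinds, starts, starts + rep(c(500, 100), 10))
  m <- hand_metrics(ev, seg(0, 6000))
  expect_equal(m$SSN, 10L)
  expect_equal(m$SSM, 10L)
  expect_equal(m$SSD, 500)
})

test_that("boundary events are clipped and assigned to their midpoint segment", {
  # stable [900, 1300) has midpoint 1100, inside the second segment
  ev <- manual_events(c("stable", "stable"), c(0, 900), c(900, 1300))
  m1 <- eye_metrics(ev, seg(0, 1000))
  m2 <- eye_metrics(ev, seg(1000, 1300, idx = 1L))
  expect_equal(m1$FN, 1L)
  expect_equal(m1$FD, 900)
  expect_equal(m2$FN, 1L)
  expect_equal(m2$FD, 300)  # clipped to [1000, 1300)
})

test_that("metrics demand event coverage of the segment", {
  ev <- manual_events("stable", 0, 500)
  expect_error(eye_metrics(ev, seg(0, 900)), "do not cover")
})

test_that("planted task metrics are recovered from ground-truth events", {
  set.seed(41)
  plan <- plan_tasks(fast_spec(seed = 41), skill_profile("intermediate"))
  g <- render_gaze_stream(plan)
  h <- render_hand_stream(plan)
  recs <- session_metrics(g$truth, h$truth, plan$markers)
  expect_equal(recs$FN, plan$planted$FN)
  expect_equal(recs$SN, plan$planted$SN)
  expect_equal(recs$SSN, plan$planted$SSN)
  expect_equal(recs$SSM, plan$planted$SSM)
  expect_equal(recs$FD, plan$planted$FD, tolerance = 1e-9)
  expect_equal(recs$SSD, plan$planted$SSD, tolerance = 1e-9)
})

test_that("clipped stable time never exceeds the window", {
  set.seed(42)
  p <- simulate_participant(fast_spec(seed = 42), skill_profile("novice_s1"))
  sess <- align_session(p$gaze, p$hand)
  segs <- segment_tasks(sess, markers = p$markers, max_task_ms = 10000)
  recs <- session_metrics(classify_events(sess$gaze),
                          classify_events(sess$hand), segs)
  win <- segs$t_end - segs$t_start
  expect_true(all(recs$FN * ifelse(is.na(recs$FD), 0, recs$FD) <= win + 1e-6))
  expect_true(all(recs$SSN * ifelse(is.na(recs$SSD), 0, recs$SSD) <= win + 1e-6))
})

test_that("group summaries aggregate per participant with sample SD", {
  recs <- data.frame(participant = c("a", "a", "b"), scenario = "S1",
                     task = c(0, 1, 0),
                     FD = c(100, 100, 140), FN = c(12, 12, 12),
                     SN = c(3, 3, 3), SSD = c(200, 200, 260),
                     SSN = c(5, 5, 5), SSM = c(2, 2, 2),
                     group = c("novice", "novice", "novice"))
  s <- summarize_metrics(recs)
  fd <- s[s$metric == "FD", ]
  expect_equal(fd$M, 120)
  expect_equal(fd$SD, sd(c(100, 140)))  # 28.284
  expect_equal(fd$n, 2L)

  single <- summarize_metrics(recs[recs$participant == "a", ])
  expect_equal(single[single$metric == "FN", "M"], 12)
  expect_equal(single[single$metric == "FN", "SD"], 0)
  expect_true(all(single$single))

  expect_error(summarize_metrics(recs[0, ]), "group")
})

test_that("participant means ignore task order and missing FD values", {
  recs <- data.frame(participant = "a", scenario = "S1", task = 0:2,
                     FD = c(100, NA, 200), FN = c(2, 0, 4), SN = 1,
                     SSD = c(50, 60, 70), SSN = 3, SSM = 2)
  m <- participant_means(recs)
  expect_equal(m$FD, 150)  # NA task excluded
  perm <- recs[c(3, 1, 2), ]
  expect_equal(participant_means(perm)$FD, m$FD)
  expect_equal(participant_means(perm)$FN, m$FN)
})

test_that("counts are invariant under time translation of the session", {
  set.seed(43)
  plan <- plan_tasks(fast_spec(seed = 43), skill_profile("novice_s1"))
  g <- render_gaze_stream(plan)
  ev <- classify_events(g$stream)
  segs <- plan$markers
  base <- vapply(seq_len(nrow(segs)),
                 function(i) eye_metrics(ev, segs[i, ])$FN, integer(1))
  ev2 <- ev
  ev2$events$t_start <- ev2$events$t_start + 12345
  ev2$events$t_end <- ev2$events$t_end + 12345
  segs2 <- segs
  segs2$t_start <- segs2$t_start + 12345
  segs2$t_end <- segs2$t_end + 12345
  shifted <- vapply(seq_len(nrow(segs2)),
                    function(i) eye_metrics(ev2, segs2[i, ])$FN, integer(1))
  expect_identical(base, shifted)
})
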