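test_that("identical spec and seed give bit-identical cohorts", {
  spec <- fast_spec(seed = 61)
  spec$n_intermediate <- 1; spec$n_novice <- 1
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$planted, c2$planted)
  expect_identical(c1$participants[[1]]$gaze$samples,
                   c2$participants[[1]]$gaze$samples)
  expect_identical(c1$participants[[2]]$hand$samples,
                   c2$participants[[2]]$hand$samples)
})

test_that("planted metrics recomputed from ground truth match the plan exactly", {
  set.seed(62)
  for (i in 1:3) {
    plan <- plan_tasks(fast_spec(seed = i), skill_profile("intermediate"))
    ev <- eyehand:::truth_event_sequence(plan$eye_events, "eye")
    hv <- eyehand:::truth_event_sequence(plan$hand_events, "tool")
    recs <- session_metrics(ev, hv, plan$markers)
    expect_equal(recs$FN, plan$planted$FN)
    expect_equal(recs$SN, plan$planted$SN)
    expect_equal(recs$SSN, plan$planted$SSN)
    expect_equal(recs$SSM, plan$planted$SSM)
    expect_equal(recs$FD, plan$planted$FD, tolerance = 1e-9)
    expect_equal(recs$SSD, plan$planted$SSD, tolerance = 1e-9)
  }
})

test_that("a plan request is honoured verbatim", {
  set.seed(63)
  plan <- make_task_plan(fn = 12, fd_ms = 400, sn = 6, ssn = 10,
                         ssd_ms = 500, ssm = 4)
  expect_equal(plan$planted$FN, 12L)
  expect_equal(plan$planted$SN, 6L)
  expect_equal(plan$planted$SSN, 10L)
  expect_equal(plan$planted$SSM, 4L)
  expect_equal(plan$planted$FD, 400, tolerance = 1e-9)
  expect_equal(sum(plan$eye_events$kind == "stable"), 12L)
})

test_that("an identity coupling leaves planted pairs uncorrelated", {
  spec <- cohort_spec(tasks_per_scenario = 500, seed = 64)
  set.seed(64)
  plan <- plan_tasks(spec, c(fd_ssd = 0, fn_ssn = 0, sn_ssm = 0))
  p <- plan$planted
  for (pair in list(c("FD", "SSD"), c("FN", "SSN"), c("SN", "SSM"))) {
    expect_lt(abs(cor(p[[pair[1]]], p[[pair[2]]], method = "spearman")), 0.1)
  }
})

test_that("a planted strong negative coupling lands in its band", {
  spec <- cohort_spec(tasks_per_scenario = 500, seed = 65)
  set.seed(65)
  plan <- plan_tasks(spec, c(fd_ssd = -0.8, fn_ssn = 0, sn_ssm = 0))
  r <- cor(plan$planted$FD, plan$planted$SSD, method = "spearman")
  expect_gt(r, -0.9)
  expect_lt(r, -0.65)
})

test_that("a non-PSD coupling matrix is rejected naming the eigenvalue", {
  sigma <- diag(6)
  sigma[1, 4] <- sigma[4, 1] <- 0.9
  sigma[1, 5] <- sigma[5, 1] <- 0.9
  sigma[4, 5] <- sigma[5, 4] <- -0.9
  expect_error(plan_tasks(fast_spec(), sigma), "not positive semi-definite.*-")
})

test_that("count and duration ranges that cannot tile a task are rejected", {
  expect_error(cohort_spec(fn_range = c(10, 30), fd_range = c(300, 500)),
               "cannot tile")
})

test_that("rendering fails when the rate cannot represent the shortest event", {
  set.seed(66)
  plan <- plan_tasks(fast_spec(seed = 66), skill_profile("novice_s1"))
  expect_error(render_gaze_stream(plan, rate_hz = 10), "too low")
})

test_that("the same plan renders to identical recovered counts at 60 and 100 Hz", {
  set.seed(67)
  for (i in 1:3) {
    plan <- plan_tasks(fast_spec(seed = 100 + i), skill_profile("intermediate"))
    g60 <- render_gaze_stream(plan, rate_hz = 60)
    g100 <- render_gaze_stream(plan, rate_hz = 100)
    k60 <- table(classify_events(g60$stream)$events$kind)
    k100 <- table(classify_events(g100$stream)$events$kind)
    expect_equal(k60[["stable"]], k100[["stable"]])
    expect_equal(k60[["rapid"]], k100[["rapid"]])
  }
})

test_that("doubling spatial amplitude leaves recovered counts unchanged", {
  set.seed(68)
  plan <- plan_tasks(fast_spec(seed = 68), skill_profile("novice_s1"))
  h <- render_hand_stream(plan)
  s <- h$stream$samples
  pos <- as.matrix(s[, c("tool_x", "tool_y", "tool_z")])
  k1 <- table(classify_events(pos, t = s$t, valid = s$valid_tool)$events$kind)
  k2 <- table(classify_events(pos * 2, t = s$t, valid = s$valid_tool)$events$kind)
  expect_identical(k1, k2)
})

test_that("optional blink injection produces extra gap events", {
  spec <- fast_spec(seed = 69, blink_rate_per_min = 40)
  set.seed(69)
  plan <- plan_tasks(spec, skill_profile("novice_s1"))
  g <- render_gaze_stream(plan)
  expect_true(any(!g$stream$samples$valid_left))
  ev <- classify_events(g$stream)
  expect_gt(sum(ev$events$kind == "gap"),
            sum(g$truth$events$kind == "gap") - 1L)
})
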