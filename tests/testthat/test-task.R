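test_that("the default layout groups targets by DOF as in the protocol", {
  lay <- make_layout()
  expect_length(lay$targets, 8)
  expect_identical(lay$dof_of[3], 1L)
  expect_identical(lay$dof_of[7], 2L)
  # 1-DOF targets sit on an axis, 2-DOF targets off both axes
  for (i in 1:4) expect_true(any(lay$targets[[i]]$center == 0))
  for (i in 5:8) expect_true(all(lay$targets[[i]]$center != 0))
  expect_error(make_layout(radius = 0), "radius")
  expect_error(make_layout(radius = 0.5), "overlap")
})

test_that("layouts round-trip through JSON", {
  lay <- make_layout(distance = 0.4, radius = 0.06)
  path <- withr::local_tempfile(fileext = ".json")
  write_layout(lay, path)
  back <- read_layout(path)
  for (i in 1:8) {
    expect_equal(back$targets[[i]]$center, lay$targets[[i]]$center)
    expect_equal(back$targets[[i]]$radius, lay$targets[[i]]$radius)
  }
})

test_that("the dwell rule on scripted traces defines reaching time", {
  tt <- seq(0, 10, by = 0.01)
  # enters at 3.0 s and never leaves
  out <- reaching_outcome(tt, tt >= 3.0)
  expect_true(out$success)
  expect_equal(out$reaching_time_s, 3.0)
  expect_equal(out$completed_at_s, 5.0)

  # enters at 2.0, exits at 3.5, re-enters at 4.0 and stays
  inside <- (tt >= 2.0 & tt < 3.5) | tt >= 4.0
  out2 <- reaching_outcome(tt, inside)
  expect_true(out2$success)
  expect_equal(out2$reaching_time_s, 4.0)
  expect_equal(out2$completed_at_s, 6.0)

  # an interrupted dwell never completes
  out3 <- reaching_outcome(tt, tt %% 1 < 0.5)
  expect_false(out3$success)
  expect_true(is.na(out3$reaching_time_s))
})

test_that("user intent picks the mapped class toward the target", {
  setup <- fixture_setup("healthy")
  user <- setup$user
  map <- motion_mapping("right_handed")
  tgt <- list(center = c(0.55, 0), radius = 0.08)

  d1 <- user_intent(user, cursor_state(), tgt, "pr", map)
  expect_identical(d1$intent$class, "WRIST_EXTENSION")
  expect_gt(d1$intent$intensity, 0)

  # inside the stop deadband the user relaxes
  d2 <- user_intent(user, cursor_state(pos = c(0.54, 0)), tgt, "pr", map)
  expect_identical(d2$intent$class, "NO_MOTION")
  expect_identical(d2$intent$intensity, 0)

  # DC with the error on the inactive axis: a switch burst is emitted first
  tgt_y <- list(center = c(0, 0.55), radius = 0.08)
  d3 <- user_intent(user, cursor_state(), tgt_y, "dc", map, dc_axis = "x")
  expect_identical(d3$intent$class, "CO_CONTRACT")
  expect_identical(d3$policy$phase, "switch")
  # trigger variant presses the remote muscle instead
  d4 <- user_intent(user, cursor_state(), tgt_y, "dc", motion_mapping("dmd"),
                    dc_axis = "x", use_trigger = TRUE)
  expect_identical(d4$intent$trigger, 1)
  expect_identical(d4$intent$class, "NO_MOTION")
})

test_that("the user anticipates coasting through the admittance time constant", {
  setup <- fixture_setup("healthy")
  user <- setup$user
  map <- motion_mapping("right_handed")
  tgt <- list(center = c(0.55, 0), radius = 0.08)
  # far from the target but coasting straight into it: relax, don't push
  cur <- cursor_state(pos = c(0.25, 0), vel = c(0.2, 0))
  d <- user_intent(user, cur, tgt, "pr", map, tau = 1.65)
  expect_identical(d$intent$class, "NO_MOTION")
  # same position at rest: push
  d2 <- user_intent(user, cursor_state(pos = c(0.25, 0)), tgt, "pr", map,
                    tau = 1.65)
  expect_identical(d2$intent$class, "WRIST_EXTENSION")
})

test_that("a trial's recorded outcome matches the dwell rule on its own trace", {
  setup <- fixture_setup("healthy")
  lay <- make_layout()
  out <- run_trial(setup$pr, setup$user, lay, 1, setup$params, seed = 31,
                   store_timeseries = TRUE)
  expect_true(out$result$success)
  ts <- attr(out$result, "timeseries")
  tgt <- lay$targets[[1]]
  inside <- sqrt((ts[, "x"] - tgt$center[1])^2 +
                   (ts[, "y"] - tgt$center[2])^2) <= tgt$radius
  audit <- reaching_outcome(ts[, "t"], inside)
  expect_equal(out$result$reaching_time_s, audit$reaching_time_s)
  expect_equal(out$result$completed_at_s - out$result$reaching_time_s, 2)
})

test_that("sessions follow the trial schedule, discard bookkeeping and seeds", {
  setup <- fixture_setup("healthy")
  spec <- session_spec("pr", "healthy", dof = 1, trials_per_target = 3,
                       discard_first = 1, seed = 5)
  s1 <- run_session(spec, setup)
  expect_identical(nrow(s1), 12L)
  # targets cycle in numerical order
  expect_identical(s1$target_id, rep(1:4, times = 3))
  expect_identical(sum(s1$discarded), 4L)
  expect_identical(s1$discarded, s1$trial_index == 1)

  # same seed reproduces the session exactly
  s2 <- run_session(spec, setup)
  expect_identical(s1, s2)
  s3 <- run_session(session_spec("pr", "healthy", dof = 1,
                                 trials_per_target = 3, discard_first = 1,
                                 seed = 6), setup)
  expect_false(identical(s1$reaching_time_s, s3$reaching_time_s))
})

test_that("the DMD protocol restricts the target set", {
  expect_identical(session_spec("dc", "dmd", 1)$target_ids, c(1L, 2L))
  expect_identical(session_spec("dc", "dmd", 2)$target_ids, c(6L, 8L))
  expect_identical(session_spec("dc", "healthy", 2)$target_ids, 5:8)
  expect_error(session_spec("dc", "dmd", 1, trials_per_target = 2,
                            discard_first = 2))
})

test_that("reaching times are positive and bounded by timeout minus dwell", {
  setup <- fixture_setup("healthy")
  lay <- make_layout()
  for (tg in c(2, 6)) {
    out <- run_trial(setup$dc, setup$user, lay, tg, setup$params, seed = tg)
    if (out$result$success) {
      expect_gt(out$result$reaching_time_s, 0)
      expect_lt(out$result$reaching_time_s, 30 - 2)
    }
  }
})
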