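test_that("time-domain features match their definitions on canonical signals", {
  # constant window above the deadband
  w <- matrix(0.5, 1, 250)
  f <- extract_features(w, deadband = 0.01)
  expect_equal(unname(f), c(0.5, 0.5, 0, 0, 0))

  # 40 Hz unit sinusoid over 250 ms: ~20 zero crossings
  x <- sin(2 * pi * 40 * seq_len(250) / 1000)
  f40 <- extract_features(matrix(x, 1), deadband = 0)
  zc <- unname(f40[3])
  expect_gte(zc, 19); expect_lte(zc, 21)
  # independent count on the raw array
  oracle_zc <- sum(x[-250] * x[-1] < 0)
  expect_equal(zc, oracle_zc)

  # monotone ramp: no slope sign change, waveform length = total rise
  ramp <- matrix(seq(0, 1, length.out = 250), 1)
  fr <- extract_features(ramp, deadband = 0)
  expect_equal(unname(fr[4]), 0)
  expect_equal(unname(fr[5]), 1)
})

test_that("feature invariants hold on random windows", {
  withr::with_seed(31, {
    for (i in seq_len(50)) {
      w <- matrix(rnorm(6 * 250, sd = runif(1, 0.01, 2)), 6, 250)
      f <- matrix(extract_features(w), nrow = 5)  # rows rms, mav, zc, ssc, wl
      expect_true(all(f[1, ] >= f[2, ]))          # RMS >= MAV (Cauchy-Schwarz)
      expect_true(all(f >= 0))
      expect_true(all(f[3:4, ] == floor(f[3:4, ])))
    }
  })
})

test_that("the training protocol yields 15 windows per rep and 375 vectors", {
  setup <- fixture_setup("healthy")
  kit <- make_calibration_kit(setup$profile, seed = 5)
  ts <- build_training_set(kit$training)
  expect_identical(nrow(ts$x), 375L)
  expect_identical(ncol(ts$x), 30L)
  expect_identical(as.vector(table(ts$y)), rep(75L, 5))

  # windows per rep by direct enumeration: starts 1, 126, ..., 1751
  expect_identical(length(myoreach:::window_starts(2000, 250, 125)), 15L)
  expect_equal(max(myoreach:::window_starts(2000, 250, 125)) + 249, 2000)

  # a short rep is rejected
  short <- kit$training
  short$HAND_OPEN[[1]] <- emg_recording(
    short$HAND_OPEN[[1]]$samples[, 1:1000], 1000,
    short$HAND_OPEN[[1]]$channel_roles)
  expect_error(build_training_set(short), "shorter")

  # a missing class is rejected
  expect_error(build_training_set(kit$training[-1]), "missing")
})

test_that("training is deterministic and accurate on separable synthetic classes", {
  setup <- fixture_setup("healthy")
  expect_gte(setup$model$meta$training_accuracy, 0.95)

  kit <- make_calibration_kit(setup$profile, seed = 7)
  ts <- build_training_set(kit$training)
  cfg <- pr_config(seed = 123)
  m1 <- suppressWarnings(pr_train(ts, cfg))
  m2 <- suppressWarnings(pr_train(ts, cfg))
  expect_identical(m1$w1, m2$w1)
  expect_identical(m1$w2, m2$w2)
})

test_that("permuted labels drop hold-out accuracy to chance", {
  setup <- fixture_setup("healthy")
  kit <- make_calibration_kit(setup$profile, seed = 8)
  ts <- build_training_set(kit$training)
  withr::with_seed(32, {
    idx <- sample(nrow(ts$x))
    train <- idx[1:250]; hold <- idx[251:375]
    perm <- list(x = ts$x[train, ], y = sample(ts$y[train]))
    m <- suppressWarnings(pr_train(perm, pr_config(seed = 99)))
    acc <- mean(pr_classify(m, ts$x[hold, ]) == as.character(ts$y[hold]))
    expect_gte(acc, 0.10)
    expect_lte(acc, 0.35)
  })
})

test_that("classification is total, deterministic and centroid-consistent", {
  setup <- fixture_setup("healthy")
  kit <- make_calibration_kit(setup$profile, seed = 6)
  ts <- build_training_set(kit$training)
  model <- suppressWarnings(pr_train(ts, pr_config(seed = 1)))

  # class centroids classify as their own class
  for (cls in MOTION_CLASSES) {
    centroid <- colMeans(ts$x[ts$y == cls, , drop = FALSE])
    expect_identical(pr_classify(model, centroid), cls)
  }
  # all-zero features look like rest
  expect_identical(pr_classify(model, rep(0, 30)), "NO_MOTION")
  # determinism
  f <- ts$x[40, ]
  expect_identical(pr_classify(model, f), pr_classify(model, f))
})

test_that("a serialized model reproduces predictions exactly", {
  setup <- fixture_setup("healthy")
  kit <- make_calibration_kit(setup$profile, seed = 6)
  ts <- build_training_set(kit$training)
  path <- withr::local_tempfile(fileext = ".json")
  write_pr_model(setup$model, path)
  back <- read_pr_model(path)
  expect_identical(pr_classify(back, ts$x), pr_classify(setup$model, ts$x))
})

test_that("pr_proportional averages voluntary envelopes against the mean MVC", {
  calib <- calibration_profile(rest_env = rep(0, 6), mvc_env = rep(1, 6),
                               channel_roles = c("fcu", "mid1", "mid2",
                                                 "mid3", "mid4", "ecu"))
  expect_equal(pr_proportional(rep(0.5, 6), calib), 0.5)
  expect_equal(pr_proportional(rep(0, 6), calib), 0)
  expect_equal(pr_proportional(rep(2, 6), calib), 1)  # clamped
  # rest subtraction happens per channel before averaging
  calib2 <- calibration_profile(rest_env = rep(0.1, 6), mvc_env = rep(1.1, 6),
                                channel_roles = calib$channel_roles)
  expect_equal(pr_proportional(rep(0.6, 6), calib2), 0.5 / calib2$mvc_mean_env)
})

test_that("pr_output routes the proportional signal per the mapping table", {
  map_r <- motion_mapping("right_handed")
  expect_equal(pr_output("WRIST_EXTENSION", 0.8, map_r), c(0.8, 0))
  expect_equal(pr_output("WRIST_FLEXION", 0.8, map_r), c(-0.8, 0))
  expect_equal(pr_output("HAND_OPEN", 0.3, map_r), c(0, 0.3))
  expect_equal(pr_output("NO_MOTION", 0.9, map_r), c(0, 0))
  expect_equal(pr_output("HAND_OPEN", 0.5, motion_mapping("dmd")), c(0.5, 0))
  expect_equal(pr_output("WRIST_FLEXION", 0.5, motion_mapping("left_handed")),
               c(0.5, 0))
})

test_that("every mapping preset is bijective per axis", {
  for (p in c("right_handed", "left_handed", "dmd")) {
    map <- motion_mapping(p)
    dirs <- do.call(rbind, map$pr[setdiff(names(map$pr), "NO_MOTION")])
    # four classes cover the four signed directions exactly once
    expect_identical(unname(sort(dirs[, 1] + 2 * dirs[, 2])), c(-2, -1, 1, 2))
    for (axis in 1:2) for (s in c(-1, 1)) {
      cls <- myoreach:::pr_class_for_direction(map, axis, s)
      expect_equal(map$pr[[cls]][axis] * s, 1)
    }
  }
})
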