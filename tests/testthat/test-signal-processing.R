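test_that("high-pass removes DC offsets and passes the sEMG band", {
  rec <- emg_recording(matrix(3.0, 6, 5000),
                       fs = 1000,
                       channel_roles = c("fcu", "mid1", "mid2", "mid3", "mid4", "ecu"))
  hp <- emg_highpass(rec)
  tail_mean <- rowMeans(abs(hp$samples[, 4001:5000]))
  expect_true(all(tail_mean < 1e-6))

  zero <- emg_recording(matrix(0, 6, 1000), 1000, rec$channel_roles)
  expect_equal(emg_highpass(zero)$samples, zero$samples)

  # 100 Hz is deep in the passband of a 2nd-order 20 Hz high-pass
  s100 <- emg_highpass(sine_recording(100))
  amp <- max(s100$samples[1, 4001:5000])
  expect_lt(abs(amp - 1.0), 0.02)
})

test_that("high-pass rejects non-finite input", {
  expect_error(emg_recording(matrix(c(NA, rep(1, 599)), 6, 100), 1000,
                             c("fcu", "mid1", "mid2", "mid3", "mid4", "ecu")),
               "finite")
})

test_that("envelope of a sinusoid settles at 2a/pi and follows amplitude steps", {
  for (a in c(1, 0.37)) {
    env <- process_emg(sine_recording(100, amp = a, dur_s = 10))
    tail_mean <- mean(env$values[1, 9001:10000])
    expect_lt(abs(tail_mean - 2 * a / pi) / (2 * a / pi), 0.03)
  }

  zero <- emg_recording(matrix(0, 6, 2000), 1000,
                        c("fcu", "mid1", "mid2", "mid3", "mid4", "ecu"))
  expect_true(all(process_emg(zero)$values == 0))

  # amplitude step a -> 2a at t = 5 s
  tt <- seq_len(10000) / 1000
  amp <- ifelse(tt <= 5, 1, 2)
  x <- matrix(rep(amp * sin(2 * pi * 100 * tt), each = 6), nrow = 6)
  env <- process_emg(emg_recording(x, 1000,
                                   c("fcu", "mid1", "mid2", "mid3", "mid4", "ecu")))
  expect_lt(abs(mean(env$values[1, 9001:10000]) - 4 / pi) / (4 / pi), 0.03)
  # rising trend between the plateaus: 100 ms bins climb from 2a/pi to 4a/pi
  # with dips no larger than the low-pass step-response ringing (~13 %)
  mid <- colMeans(matrix(env$values[1, 4501:6500], nrow = 100))
  expect_lt(abs(mid[1] - 2 / pi), 0.03 * 2 / pi)
  expect_lt(abs(mid[length(mid)] - 4 / pi), 0.03 * 4 / pi)
  expect_true(all(diff(mid) > -0.15 * 2 / pi))
  expect_true(all(cummax(mid) <= 1.15 * 4 / pi))
})

test_that("envelope pipeline is positively homogeneous up to the rectifier", {
  withr::with_seed(11, {
    x <- matrix(rnorm(6 * 3000), 6, 3000)
    rec1 <- emg_recording(x, 1000, c("fcu", "mid1", "mid2", "mid3", "mid4", "ecu"))
    for (k in c(3.7, 0.01)) {
      reck <- emg_recording(k * x, 1000, rec1$channel_roles)
      e1 <- process_emg(rec1)$values[, 2001:3000]
      ek <- process_emg(reck)$values[, 2001:3000]
      expect_lt(max(abs(ek - k * e1)) / max(k * e1), 1e-8)
    }
  })
})

test_that("chunked streaming with state carryover equals one-shot filtering", {
  withr::with_seed(12, {
    x <- matrix(rnorm(6 * 2000), 6, 2000)
    rec <- emg_recording(x, 1000, c("fcu", "mid1", "mid2", "mid3", "mid4", "ecu"))
    batch <- process_emg(rec)$values

    stream <- emg_stream(6, 1000)
    got <- matrix(0, 6, 0)
    splits <- c(1, 7, 250, 251, 1000, 2000)  # ragged chunk boundaries
    i <- 1
    for (s in splits) {
      out <- emg_stream_step(stream, x[, i:min(s + i - 1, 2000), drop = FALSE])
      stream <- out$stream
      got <- cbind(got, out$env)
      i <- i + s
      if (i > 2000) break
    }
    expect_lt(max(abs(got - batch[, seq_len(ncol(got))])), 1e-9)
  })
})

test_that("Butterworth stages have their -3 dB points at 2 and 20 Hz", {
  # analytic response computed from the polynomials, independent of the
  # time-domain path
  hp <- myoreach:::butter_coef(2, 20, 1000, "high")
  lp <- myoreach:::butter_coef(4, 2, 1000, "low")
  expect_lt(abs(freq_response_mag(hp$b, hp$a, 20, 1000) - 1 / sqrt(2)), 0.01 / sqrt(2))
  expect_lt(abs(freq_response_mag(lp$b, lp$a, 2, 1000) - 1 / sqrt(2)), 0.01 / sqrt(2))
  # passband gains are unity
  expect_lt(abs(freq_response_mag(hp$b, hp$a, 450, 1000) - 1), 0.01)
  expect_lt(abs(freq_response_mag(lp$b, lp$a, 0, 1000) - 1), 1e-6)
})

test_that("calibration extracts rest and MVC levels and rejects degenerates", {
  setup <- fixture_setup("healthy")
  kit <- make_calibration_kit(setup$profile, seed = 9)
  calib <- calibrate(kit$mvc, kit$rest)
  fore <- 1:6
  expect_true(all(calib$mvc_env[fore] > 10 * calib$rest_env[fore]))
  expect_equal(calib$mvc_mean_env, mean(calib$mvc_env[fore]))

  # rest recording identical to MVC: voluntary range collapses
  expect_error(calibrate(kit$mvc, kit$mvc), "calibration")
  expect_error(calibrate(kit$mvc, emg_recording(kit$rest$samples[, 1:2000],
                                                1000, kit$rest$channel_roles)),
               "at least")
})

test_that("mvc_mean_env is the arithmetic mean of the six forearm channels", {
  calib <- calibration_profile(rest_env = rep(0, 6), mvc_env = 1:6,
                               channel_roles = c("fcu", "mid1", "mid2",
                                                 "mid3", "mid4", "ecu"))
  expect_identical(calib$mvc_mean_env, 3.5)
})

test_that("voluntary envelope subtracts rest and clamps at zero", {
  calib <- calibration_profile(rest_env = c(0.1, 0.1), mvc_env = c(0.5, 1.0),
                               channel_roles = c("fcu", "ecu"))
  env <- envelope_series(matrix(c(0.1, 0.1, 0.05, 0.02, 0.6, 0.6), 2),
                         fs = 1000)
  v <- voluntary(env, calib)
  expect_equal(v$values[, 1], c(0, 0))          # env == rest
  expect_equal(v$values[, 2], c(0, 0))          # below rest clamps, not negative
  expect_equal(v$values[1, 3], 0.5)             # 0.6 - 0.1
  expect_true(all(v$values >= 0))
})

test_that("recordings round-trip through CSV + sidecar", {
  withr::with_seed(3, {
    rec <- emg_recording(matrix(rnorm(6 * 100), 6, 100), 1000,
                         c("fcu", "mid1", "mid2", "mid3", "mid4", "ecu"),
                         subject_profile_id = "demo")
    path <- withr::local_tempfile(fileext = ".csv")
    write_recording(rec, path)
    back <- read_recording(path)
    expect_equal(back$samples, rec$samples, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_identical(back$channel_roles, rec$channel_roles)
    expect_identical(back$subject_profile_id, "demo")
  })
})

test_that("calibration profiles round-trip through JSON", {
  calib <- pair_calib()
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(calib, path)
  back <- read_calibration(path)
  expect_equal(back$rest_env, calib$rest_env)
  expect_equal(back$mvc_env, calib$mvc_env)
  expect_equal(back$mvc_mean_env, calib$mvc_mean_env)
})
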