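test_that("resampling is exact at the native rate and on closed forms", {
  s <- constant_velocity_series(rate_hz = 100, duration = 1, velocity_dps = 40)
  same <- resample_orientation(s, 100)
  expect_equal(same$t, s$t, tolerance = 1e-12)
  expect_lt(max(abs(same$q - s$q)), 1e-9)

  # constant orientation stays constant at any rate
  n <- neutral_series(rate_hz = 60, duration = 1)
  up <- resample_orientation(n, 250)
  expect_lt(max(global_rotation_angle(up$q)), 1e-9)

  # linear-in-time rotation: resampled angles match the closed form
  res <- resample_orientation(s, 73)
  expect_equal(global_rotation_angle(res$q), 40 * res$t, tolerance = 1e-6)

  expect_error(resample_orientation(s, -1), "positive")
})

test_that("resampled validity is propagated conservatively", {
  s <- constant_velocity_series(rate_hz = 50, duration = 1)
  s$valid[10] <- FALSE
  res <- resample_orientation(s, 100)
  # interpolated points adjacent to the invalid sample are invalid
  bad_t <- s$t[10]
  near <- which(abs(res$t - bad_t) < 1 / 50 - 1e-9 & abs(res$t - bad_t) > 1e-9)
  expect_true(all(!res$valid[near]))
  far <- which(abs(res$t - bad_t) > 2 / 50)
  expect_true(all(res$valid[far]))
})

test_that("synchronize recovers integer lags exactly on clean signals", {
  s <- raised_cosine_series(rate_hz = 100)
  n <- length(s$t)
  for (k in c(0L, 17L, -40L, 120L, 200L)) {
    if (k >= 0) {
      b <- orientation_series(s$t, s$q[c(rep(1, k), 1:(n - k)), , drop = FALSE],
                              source = "reference")
    } else {
      b <- orientation_series(s$t, s$q[c((-k + 1):n, rep(n, -k)), , drop = FALSE],
                              source = "reference")
    }
    sync <- synchronize(s, b, require_neutral_prefix = FALSE)
    expect_identical(sync$lag_samples, k)
    expect_gt(sync$peak_correlation, 0.999)
  }
})

test_that("synchronize selects the dominant plane and rejects flat signals", {
  s <- raised_cosine_series(axis = c(0, 0, 1))  # rotation plane (z)
  sync <- synchronize(s, s)
  expect_identical(sync$lag_samples, 0L)
  expect_identical(sync$channel_used, "rotation")

  flat <- neutral_series(rate_hz = 100, duration = 3)
  expect_error(synchronize(flat, flat), "unsynchronizable")

  moving_start <- constant_velocity_series(velocity_dps = 30, duration = 3)
  expect_error(synchronize(moving_start, moving_start), "quasi-neutral")
})

test_that("noisy 0.25 s lags are recovered within one sample", {
  errs <- vapply(1:20, function(seed) {
    chain <- spine_chain("cervical")
    truth <- generate_trajectory(chain, "rotation", period = 4, cycles = 2,
                                 amplitude = 30, rate = 100)
    q <- spineval:::chain_orientation_quat(chain, truth$theta)
    man <- orientation_series(truth$t, q, source = "mannequin")
    noise <- noise_model(mocap_noise_sd = 0.5, obstruction_prob_at_peak = 0,
                         time_lag = 0.25, base_offset_deg = 0,
                         sensor_offset_deg = 0)
    ref <- simulate_mocap(man, noise, rate = 100, seed = seed)
    sync <- synchronize(man, ref)
    abs(sync$lag_samples - 25L)
  }, 0)
  expect_true(all(errs <= 1))
})

test_that("outlier detection flags teleports but not fast smooth motion", {
  n <- neutral_series(rate_hz = 100, duration = 2)
  expect_false(any(detect_outliers(n)))

  tele <- n
  tele$q[100, ] <- quat_from_axis_angle(c(0, 1, 0), 10)  # 10 deg jump at 100 Hz
  m <- detect_outliers(tele)
  expect_true(all(m[c(99, 100, 101)]))
  expect_identical(sum(m), 3L)

  # sinusoid with 90 deg/s peak velocity: amplitude*2*pi/period = 90
  t <- seq(0, 4, by = 0.01)
  ang <- (90 / (2 * pi)) * sin(2 * pi * t)
  q <- do.call(rbind, lapply(ang, function(a) quat_from_axis_angle(c(1, 0, 0), a)))
  smooth <- orientation_series(t, q, source = "reference")
  expect_false(any(detect_outliers(smooth, velocity_threshold = 120)))
})

test_that("outlier flags are stable under doubling the sampling rate", {
  make <- function(rate) {
    t <- seq(0, 4, by = 1 / rate)
    ang <- (90 / (2 * pi)) * sin(2 * pi * t)
    ang[t > 1.5 & t < 1.6] <- ang[t > 1.5 & t < 1.6] + 15  # corrupted interval
    q <- do.call(rbind, lapply(ang, function(a) quat_from_axis_angle(c(1, 0, 0), a)))
    orientation_series(t, q, source = "reference")
  }
  for (rate in c(100, 200)) {
    s <- make(rate)
    m <- detect_outliers(s)
    flagged_t <- range(s$t[m])
    expect_equal(flagged_t[1], 1.5, tolerance = 2 / rate)
    expect_equal(flagged_t[2], 1.6, tolerance = 2 / rate)
  }
})

test_that("repair follows the 50% window rule and matches closed forms", {
  s <- constant_velocity_series(rate_hz = 100, duration = 2, velocity_dps = 20)
  truth_q <- s$q

  # 1 corrupted sample in a 0.2 s window (5%): repaired by slerp
  mask <- rep(FALSE, length(s$t))
  mask[50] <- TRUE
  corrupted <- s
  corrupted$q[50, ] <- quat_from_axis_angle(c(0, 1, 0), 45)
  fixed <- repair_series(corrupted, mask)
  expect_true(fixed$valid[50])
  expect_lt(max(abs(fixed$q[50, ] - truth_q[50, ])), 1e-6)
  # unflagged samples untouched
  expect_identical(fixed$q[-50, ], corrupted$q[-50, ])

  # 60% of a window corrupted: left invalid
  mask2 <- rep(FALSE, length(s$t))
  mask2[100:111] <- TRUE  # 12 of every surrounding 20-sample window
  fixed2 <- repair_series(s, mask2)
  expect_true(all(!fixed2$valid[103:108]))

  expect_error(repair_series(s, rep(TRUE, length(s$t))), "irreparable")
  expect_error(repair_series(s, mask[-1]), "align")
})

test_that("simulated obstruction bursts are caught by the outlier rule", {
  hit_rates <- vapply(1:20, function(seed) {
    chain <- spine_chain("cervical")
    truth <- generate_trajectory(chain, "flexion", period = 4, cycles = 2,
                                 amplitude = 35, rate = 100)
    q <- spineval:::chain_orientation_quat(chain, truth$theta)
    man <- orientation_series(truth$t, q, source = "mannequin")
    noise <- noise_model(mocap_noise_sd = 0.1, obstruction_prob_at_peak = 1,
                         time_lag = 0, base_offset_deg = 0, sensor_offset_deg = 0)
    ref <- simulate_mocap(man, noise, rate = 120, seed = seed)
    bursts <- unlist(attr(ref, "artifacts")$bursts)
    if (!length(bursts)) return(1)
    mean(detect_outliers(ref)[bursts])
  }, 0)
  expect_gt(mean(hit_rates), 0.9)
})
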