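test_that("trajectories respect the design arithmetic and stay under 120 deg/s", {
  chain <- spine_chain("cervical")
  tr <- generate_trajectory(chain, "flexion", period = 4, cycles = 3,
                            amplitude = 40, rate = 100, neutral_prefix = 1)
  expect_equal(max(tr$t), 13)  # 1 s prefix + 3 cycles x 4 s
  # flexion condition: only flexion-mapped joints move
  planes <- vapply(chain$rows, `[[`, "", "plane")
  idx <- vapply(chain$rows, function(r)
    if (identical(r$joint_index, "fixed")) NA_integer_ else r$joint_index, 1L)
  flexion_joints <- idx[!is.na(idx) & planes == "flexion"]
  expect_true(all(abs(tr$theta[, setdiff(1:4, flexion_joints)]) == 0))
  expect_equal(max(rowSums(tr$theta)), 40, tolerance = 1e-6)
  # starts and ends neutral
  expect_equal(tr$theta[1, ], tr$theta[nrow(tr$theta), ], ignore_attr = TRUE)

  # finite-difference peak global velocity stays under the threshold
  peak_velocity <- function(condition, period, amplitude) {
    tj <- generate_trajectory(chain, condition, period = period,
                              amplitude = amplitude, rate = 100)
    q <- spineval:::chain_orientation_quat(chain, tj$theta)
    step <- global_rotation_angle(relative_rotation(q[-nrow(q), ], q[-1, ]))
    max(step) * 100
  }
  for (cond in c("flexion", "lateral_flexion", "rotation", "combined")) {
    expect_lt(peak_velocity(cond, 4, 40), 120)  # slow default
    expect_lt(peak_velocity(cond, 1, 15), 120)  # fast default
  }
  expect_warning(generate_trajectory(chain, "rotation", period = 1,
                                     amplitude = 60, rate = 100),
                 "outlier threshold")
})

test_that("encoder simulation quantises to the grid and bounds its error", {
  chain <- spine_chain("lumbar")
  truth <- generate_trajectory(chain, "combined", period = 4, cycles = 2,
                               amplitude = 40, rate = 100)
  enc <- simulate_encoders(truth, noise_model())
  q <- 0.0219
  expect_lt(max(abs(enc$theta / q - round(enc$theta / q))), 1e-9)
  expect_lte(max(abs(enc$theta - truth$theta)), q / 2 + 1e-12)
  expect_equal(enc$quantization, q)
})

test_that("backlash produces the expected direction-reversal hysteresis", {
  # slow triangle wave: steady-state lag equals backlash/2 on each branch,
  # so the gap between rising and falling readings at the same input is b
  t <- seq(0, 8, by = 0.01)
  x <- 10 * (1 - abs((t %% 4) / 2 - 1))  # 0 -> 10 -> 0 triangle
  truth <- joint_angle_series(t, cbind(x, 0, 0, 0), segment = "lumbar")
  nm <- noise_model(encoder_backlash = 0.5, encoder_quantization = 0)
  enc <- simulate_encoders(truth, nm)
  rising <- which(t > 0.5 & t < 1.5)          # steady rising branch
  falling <- which(t > 2.5 & t < 3.5)         # steady falling branch
  expect_equal(max(x[rising] - enc$theta[rising, 1]), 0.25, tolerance = 1e-6)
  expect_equal(max(enc$theta[falling, 1] - x[falling]), 0.25, tolerance = 1e-6)
})

test_that("noise-free mocap reproduces the truth up to resampling", {
  chain <- spine_chain("cervical")
  truth <- generate_trajectory(chain, "combined", period = 4, cycles = 2,
                               amplitude = 30, rate = 100)
  man <- orientation_series(truth$t,
                            spineval:::chain_orientation_quat(chain, truth$theta),
                            source = "mannequin")
  ref <- simulate_mocap(man, noise_free(), rate = 120, seed = 1)
  at_truth <- spineval:::sample_orientation_at(man, ref$t)
  err <- global_rotation_angle(relative_rotation(ref$q, at_truth))
  expect_lt(max(err), 1e-6)
})

test_that("default study matches the trial grid and is seed-reproducible", {
  des <- study_design(seed = 3)
  st <- generate_study(des, noise_model())
  expect_length(st$trials, 80)
  seg <- vapply(st$trials, `[[`, "", "segment")
  spd <- vapply(st$trials, `[[`, "", "speed")
  expect_equal(sum(seg == "cervical"), 40)
  expect_equal(sum(seg == "lumbar"), 40)
  expect_equal(unname(table(spd, seg)["fast", ]), c(20, 20), ignore_attr = TRUE)
  expect_named(st$calibration, c("cervical", "lumbar"))

  st2 <- generate_study(study_design(seed = 3), noise_model())
  expect_identical(st$trials[["cervical_flexion_fast1"]]$encoders$theta,
                   st2$trials[["cervical_flexion_fast1"]]$encoders$theta)
  expect_identical(st$trials[["lumbar_rotation_slow4"]]$mocap$q,
                   st2$trials[["lumbar_rotation_slow4"]]$mocap$q)
  # different seed, different noise draws
  st3 <- generate_study(study_design(seed = 4), noise_model())
  expect_false(identical(st$trials[[1]]$mocap$q, st3$trials[[1]]$mocap$q))
})

test_that("the ground-truth ledger reconstructs every injected corruption", {
  nm <- noise_model(dropout_trials = "cervical_rotation_slow1",
                    obstruction_mode = "jitter")
  des <- study_design(reps_per_condition = 2, seed = 9)
  st <- generate_study(des, nm)
  led <- st$ledger
  expect_equal(led$time_lag, 0.25)
  expect_equal(global_rotation_angle(led$base_offset), 7, tolerance = 1e-9)
  expect_equal(global_rotation_angle(led$sensor_offset), 4, tolerance = 1e-9)
  expect_length(led$encoder_zero$cervical, 4)
  expect_named(led$artifacts, names(st$trials))
  # dropout trial id recorded and its invalid window present
  expect_identical(led$dropout_trials, "cervical_rotation_slow1")
  tr <- st$trials[["cervical_rotation_slow1"]]
  expect_false(all(tr$mocap$valid))
  expect_identical(which(!tr$mocap$valid), tr$artifacts$dropout)
})

test_that("median pipeline error grows with mocap noise", {
  chain <- spine_chain("cervical")
  rmse_at <- function(sd, seed) {
    truth <- generate_trajectory(chain, "flexion", period = 4, cycles = 2,
                                 amplitude = 30, rate = 50)
    man <- orientation_series(truth$t,
                              spineval:::chain_orientation_quat(chain, truth$theta),
                              source = "mannequin")
    nm <- noise_model(mocap_noise_sd = sd, obstruction_prob_at_peak = 0,
                      time_lag = 0, base_offset_deg = 0, sensor_offset_deg = 0)
    ref <- simulate_mocap(man, nm, rate = 50, seed = seed)
    ga_m <- global_rotation_angle(man$q)
    ga_r <- global_rotation_angle(ref$q)
    n <- min(length(ga_m), length(ga_r))
    rmse(ga_m[1:n], ga_r[1:n])
  }
  med <- vapply(c(0.2, 0.5, 1.0), function(sd) {
    stats::median(vapply(1:7, function(s) rmse_at(sd, s), 0))
  }, 0)
  expect_true(all(diff(med) > 0))
})
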