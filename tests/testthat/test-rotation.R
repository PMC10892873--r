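test_that("matrix/quaternion conversions close the round trip", {
  expect_equal(matrix_to_quaternion(diag(3)), c(1, 0, 0, 0))
  Rz180 <- matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3, 3)
  expect_equal(matrix_to_quaternion(Rz180), c(0, 0, 0, 1), tolerance = 1e-12)

  q <- random_quaternions(100, seed = 42)
  worst <- 0
  for (i in seq_len(nrow(q))) {
    R <- quaternion_to_matrix(q[i, ])
    back <- quaternion_to_matrix(matrix_to_quaternion(R))
    worst <- max(worst, max(abs(back - R)))
  }
  expect_lt(worst, 1e-8)
  # canonical hemisphere
  expect_true(all(quat_normalize(q)[, 1] >= 0))
})

test_that("invalid rotations are rejected", {
  expect_error(matrix_to_quaternion(diag(3) * 1.1), "not a proper rotation")
  refl <- diag(c(1, 1, -1))  # determinant -1
  expect_error(matrix_to_quaternion(refl), "not a proper rotation")
  expect_error(quat_normalize(c(0, 0, 0, 0)), "zero-norm")
})

test_that("quaternion_to_matrix honours axis-angle cases and double cover", {
  expect_equal(quaternion_to_matrix(c(1, 0, 0, 0)), diag(3))
  qx90 <- c(cos(pi / 4), sin(pi / 4), 0, 0)
  Rx90 <- matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3)
  expect_equal(quaternion_to_matrix(qx90), Rx90, tolerance = 1e-12)
  q <- drop(random_quaternions(1, seed = 3))
  expect_equal(quaternion_to_matrix(q), quaternion_to_matrix(-q))
})

test_that("global rotation angle matches the trace closed form", {
  expect_equal(global_rotation_angle(c(1, 0, 0, 0)), 0)
  # same 30 deg magnitude regardless of axis
  for (axis in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1), c(-2, 1, 3))) {
    expect_equal(global_rotation_angle(quat_from_axis_angle(axis, 30)), 30,
                 tolerance = 1e-9)
  }
  q <- random_quaternions(50, seed = 7)
  for (i in seq_len(nrow(q))) {
    R <- quaternion_to_matrix(q[i, ])
    trace_angle <- acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
    expect_equal(global_rotation_angle(q[i, ]), trace_angle, tolerance = 1e-9)
    expect_equal(global_rotation_angle(-q[i, ]), trace_angle, tolerance = 1e-9)
  }
})

test_that("relative_rotation satisfies its defining identity", {
  q <- random_quaternions(40, seed = 11)
  a <- q[1:20, ]; b <- q[21:40, ]
  r <- relative_rotation(a, b)
  recomposed <- quat_multiply(a, r)
  # compare as rotations (hemisphere-canonical)
  expect_lt(max(abs(recomposed - quat_normalize(b))), 1e-9)
  expect_equal(drop(relative_rotation(a[1, ], a[1, ])), c(1, 0, 0, 0),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(drop(relative_rotation(c(1, 0, 0, 0), b[1, ])),
               drop(quat_normalize(b[1, ])), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("slerp interpolates geodesically", {
  qa <- drop(random_quaternions(1, seed = 5))
  qb <- drop(random_quaternions(1, seed = 6))
  expect_equal(drop(quat_slerp(qa, qb, 0)), qa, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(drop(quat_slerp(qa, qb, 1)), drop(quat_normalize(qb)),
               tolerance = 1e-12, ignore_attr = TRUE)

  mid <- quat_slerp(c(1, 0, 0, 0), quat_from_axis_angle(c(0, 0, 1), 60), 0.5)
  expect_equal(drop(mid), drop(quat_from_axis_angle(c(0, 0, 1), 30)),
               tolerance = 1e-9, ignore_attr = TRUE)

  # angle proportionality on random pairs
  full <- global_rotation_angle(relative_rotation(qa, qb))
  for (t in c(0.1, 0.25, 0.5, 0.9)) {
    part <- global_rotation_angle(relative_rotation(qa, quat_slerp(qa, qb, t)))
    expect_equal(part, t * full, tolerance = 1e-6)
  }
})

test_that("anatomical decomposition recomposes exactly outside gimbal lock", {
  conv <- anatomical_convention()
  ident <- decompose_anatomical(diag(3), conv)
  expect_equal(unlist(ident[c("flexion", "lateral_flexion", "rotation")]),
               c(flexion = 0, lateral_flexion = 0, rotation = 0))

  # pure flexion about the designated axis
  Rflex <- quaternion_to_matrix(recompose_anatomical(30, 0, 0, conv))
  d <- decompose_anatomical(Rflex, conv)
  expect_equal(d$flexion, 30, tolerance = 1e-9)
  expect_equal(d$lateral_flexion, 0, tolerance = 1e-9)
  expect_equal(d$rotation, 0, tolerance = 1e-9)

  # property: decompose then recompose over random rotations
  q <- random_quaternions(200, seed = 13)
  d <- decompose_anatomical(q, conv)
  keep <- !d$degenerate
  back <- recompose_anatomical(d$flexion[keep], d$lateral_flexion[keep],
                               d$rotation[keep], conv)
  for (i in seq_len(sum(keep))) {
    err <- max(abs(quaternion_to_matrix(back[i, ]) -
                     quaternion_to_matrix(q[which(keep)[i], ])))
    expect_lt(err, 1e-8)
  }
})

test_that("alternate conventions and sequences round-trip too", {
  conv <- anatomical_convention(flexion = "x", lateral_flexion = "z",
                                rotation = "-y",
                                order = c("rotation", "flexion", "lateral_flexion"))
  q <- random_quaternions(50, seed = 17)
  d <- decompose_anatomical(q, conv)
  keep <- !d$degenerate
  back <- recompose_anatomical(d$flexion[keep], d$lateral_flexion[keep],
                               d$rotation[keep], conv)
  idx <- which(keep)
  for (i in seq_along(idx)) {
    expect_lt(max(abs(quaternion_to_matrix(back[i, ]) -
                        quaternion_to_matrix(q[idx[i], ]))), 1e-8)
  }
  expect_error(anatomical_convention(flexion = "x", lateral_flexion = "x"),
               "distinct axes")
})

test_that("gimbal lock is flagged, not silently resolved", {
  conv <- anatomical_convention()
  # middle angle (lateral flexion on axis x) at 90 deg
  q_lock <- recompose_anatomical(25, 90, 10, conv)
  d <- decompose_anatomical(q_lock, conv)
  expect_true(d$degenerate)
  # just outside the 0.5 deg guard band: not flagged
  q_near <- recompose_anatomical(25, 88, 10, conv)
  expect_false(decompose_anatomical(q_near, conv)$degenerate)
})
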