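# Shared fixtures, built in code.

random_quaternions <- function(n, seed = 1) {
  withr::with_seed(seed, {
    q <- matrix(rnorm(4 * n), ncol = 4)
  })
  quat_normalize(q)
}

random_rotation <- function(seed = 1) {
  quaternion_to_matrix(random_quaternions(1, seed))
}

# A constant-rate orientation series rotating about one axis at a constant
# angular velocity (deg/s); closed-form angle trace = rate_dps * t.
constant_velocity_series <- function(rate_hz = 100, duration = 2,
                                     axis = c(0, 0, 1), velocity_dps = 30,
                                     source = "reference") {
  t <- seq(0, duration, by = 1 / rate_hz)
  q <- do.call(rbind, lapply(t, function(ti) {
    quat_from_axis_angle(axis, velocity_dps * ti)
  }))
  orientation_series(t, q, source = source, frame = "lab")
}

# Identity-orientation series (neutral pose) of given duration.
neutral_series <- function(rate_hz = 100, duration = 1, source = "reference") {
  t <- seq(0, duration, by = 1 / rate_hz)
  orientation_series(t, matrix(rep(c(1, 0, 0, 0), length(t)), ncol = 4,
                               byrow = TRUE), source = source)
}

# Single-axis raised-cosine orientation series with a 1 s neutral prefix,
# the waveform used across sync/outlier tests.
raised_cosine_series <- function(rate_hz = 100, period = 4, cycles = 3,
                                 amplitude = 30, prefix = 1,
                                 axis = c(0, 0, 1), source = "reference") {
  t <- seq(0, prefix + cycles * period, by = 1 / rate_hz)
  phase <- pmax(0, t - prefix)
  ang <- amplitude * 0.5 * (1 - cos(2 * pi * phase / period))
  q <- do.call(rbind, lapply(ang, function(a) quat_from_axis_angle(axis, a)))
  orientation_series(t, q, source = source, frame = "lab")
}
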