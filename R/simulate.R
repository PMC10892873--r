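#' @title Synthetic dual-system validation study
#'
#' @description
#' Generates the full two-system study design with known ground truth: per
#' spine segment, one calibration trial (combined motion) plus four motion
#' conditions (flexion, lateral flexion, rotation, combined), each repeated
#' ten times -- five fast (1 s/cycle) and five slow (4 s/cycle) -- with
#' three raised-cosine cycles per trial and a one-second neutral prefix,
#' i.e. 80 measurement trials (40 per segment). The encoder stream is
#' quantised (0.0219 deg grid, with an optional backlash option emulating a
#' loose mechanism); the reference stream is resampled to its own rate,
#' delayed by an unknown lag, rotated by constant frame offsets, perturbed
#' by isotropic rotational noise, and hit by occlusion-like jitter bursts
#' concentrated near the amplitude extremes. Every injected corruption is
#' recorded in a ground-truth ledger so recovery can be tested exactly.
#'
#' @name synthetic
NULL

#' Study design parameters
#'
#' Defaults mirror the validation protocol: 2 segments x 4 conditions x
#' (5 fast + 5 slow) trials of 3 cycles each. Amplitudes are not published
#' for the original protocol; the defaults (40 deg at slow speed, 15 deg at
#' fast) keep true peak global velocity below the 120 deg/s outlier
#' threshold at both speeds.
#'
#' @param segments segments to simulate.
#' @param conditions motion conditions.
#' @param reps_per_condition trials per condition (split evenly fast/slow).
#' @param cycles_per_trial movement cycles per trial.
#' @param fast_period,slow_period seconds per cycle.
#' @param neutral_prefix seconds of neutral pose before motion onset.
#' @param encoder_rate,mocap_rate sampling rates in Hz.
#' @param amplitude_fast,amplitude_slow peak plane amplitude in degrees.
#' @param seed master seed; all trial-level randomness derives from it.
#' @return a `study_design` list.
#' @export
study_design <- function(segments = c("cervical", "lumbar"),
                         conditions = c("flexion", "lateral_flexion",
                                        "rotation", "combined"),
                         reps_per_condition = 10, cycles_per_trial = 3,
                         fast_period = 1, slow_period = 4,
                         neutral_prefix = 1,
                         encoder_rate = 100, mocap_rate = 120,
                         amplitude_fast = 15, amplitude_slow = 40,
                         seed = 1) {
  if (reps_per_condition %% 2 != 0) {
    stopf("reps_per_condition must be even (half fast, half slow)")
  }
  structure(list(segments = segments, conditions = conditions,
                 reps_per_condition = reps_per_condition,
                 cycles_per_trial = cycles_per_trial,
                 fast_period = fast_period, slow_period = slow_period,
                 neutral_prefix = neutral_prefix,
                 encoder_rate = encoder_rate, mocap_rate = mocap_rate,
                 amplitude_fast = amplitude_fast,
                 amplitude_slow = amplitude_slow,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Noise and corruption model
#'
#' @param encoder_quantization encoder grid step in degrees.
#' @param encoder_backlash hysteresis width in degrees (0 = rigid mechanism;
#'   a positive value emulates play in a looser segment).
#' @param mocap_noise_sd isotropic rotational noise of the reference, as the
#'   RMS rotation angle in degrees per sample.
#' @param obstruction_prob_at_peak probability of an occlusion burst per
#'   excursion into the top 10% of the trial's range of motion.
#' @param obstruction_burst burst duration in seconds.
#' @param obstruction_mode `"jitter"` (high-velocity oscillation) or
#'   `"dropout"` (samples marked invalid).
#' @param time_lag reference-stream delay in seconds.
#' @param base_offset_deg,base_offset_axis constant reference-side frame
#'   rotation.
#' @param sensor_offset_deg,sensor_offset_axis constant body-side frame
#'   rotation.
#' @param encoder_zero_sd SD (degrees) of the per-segment residual encoder
#'   zero offsets left over from jig calibration.
#' @param dropout_trials trial ids to hit with a prolonged reference loss
#'   (these become irreparable and must be discarded downstream).
#' @param dropout_duration length of the prolonged loss in seconds.
#' @return a `noise_model` list.
#' @export
noise_model <- function(encoder_quantization = 0.0219, encoder_backlash = 0,
                        mocap_noise_sd = 0.2,
                        obstruction_prob_at_peak = 0.3,
                        obstruction_burst = 0.15,
                        obstruction_mode = c("jitter", "dropout"),
                        time_lag = 0.25,
                        base_offset_deg = 7, base_offset_axis = c(0, 0, 1),
                        sensor_offset_deg = 4, sensor_offset_axis = c(1, 0, 0),
                        encoder_zero_sd = 0.3,
                        dropout_trials = character(0),
                        dropout_duration = 2) {
  obstruction_mode <- match.arg(obstruction_mode)
  stopifnot(encoder_quantization >= 0, encoder_backlash >= 0,
            mocap_noise_sd >= 0, obstruction_prob_at_peak >= 0,
            obstruction_prob_at_peak <= 1, time_lag >= 0)
  structure(list(encoder_quantization = encoder_quantization,
                 encoder_backlash = encoder_backlash,
                 mocap_noise_sd = mocap_noise_sd,
                 obstruction_prob_at_peak = obstruction_prob_at_peak,
                 obstruction_burst = obstruction_burst,
                 obstruction_mode = obstruction_mode,
                 time_lag = time_lag,
                 base_offset = drop(quat_from_axis_angle(base_offset_axis, base_offset_deg)),
                 sensor_offset = drop(quat_from_axis_angle(sensor_offset_axis, sensor_offset_deg)),
                 encoder_zero_sd = encoder_zero_sd,
                 dropout_trials = dropout_trials,
                 dropout_duration = dropout_duration),
            class = "noise_model")
}

#' Noise-free model
#'
#' All corruption switched off (zero quantization, noise, lag and offsets);
#' useful for pipeline floor tests.
#' @return a `noise_model`.
#' @export
noise_free <- function() {
  noise_model(encoder_quantization = 0, mocap_noise_sd = 0,
              obstruction_prob_at_peak = 0, time_lag = 0,
              base_offset_deg = 0, sensor_offset_deg = 0,
              encoder_zero_sd = 0)
}

condition_amplitudes <- function(chain, condition, amplitude) {
  planes <- vapply(chain$rows, `[[`, "", "plane")
  idx <- vapply(chain$rows, function(r)
    if (identical(r$joint_index, "fixed")) NA_integer_ else r$joint_index, 1L)
  amp <- numeric(4)
  target <- if (condition == "combined") {
    c("flexion", "lateral_flexion", "rotation")
  } else condition
  for (p in target) {
    joints <- idx[!is.na(idx) & planes == p]
    if (!length(joints)) stopf("chain has no joint in plane '%s'", p)
    amp[joints] <- amplitude / length(joints)
  }
  amp
}

#' Generate a ground-truth joint trajectory
#'
#' Raised-cosine cycles (`A/2 * (1 - cos(2 pi t / T))`) on the joints mapped
#' to the condition's plane(s): the waveform is C1-smooth, starts and ends
#' neutral, and its peak plane velocity is `A * pi / T`. A design warning is
#' emitted if the realised peak global velocity reaches the 120 deg/s
#' outlier threshold, since genuine motion must stay below it.
#'
#' @param chain a `dh_chain` (provides the joint-to-plane mapping).
#' @param condition `"flexion"`, `"lateral_flexion"`, `"rotation"` or
#'   `"combined"`.
#' @param period seconds per cycle.
#' @param cycles number of cycles.
#' @param amplitude peak plane amplitude in degrees (split across the
#'   plane's joints).
#' @param rate sampling rate in Hz.
#' @param neutral_prefix seconds of neutral pose before motion.
#' @param velocity_limit design velocity bound in deg/s (default 120).
#' @return a [joint_angle_series()] of ground-truth angles.
#' @export
generate_trajectory <- function(chain, condition, period, cycles = 3,
                                amplitude = 40, rate = 100,
                                neutral_prefix = 1, velocity_limit = 120) {
  amp <- condition_amplitudes(chain, condition, amplitude)
  duration <- neutral_prefix + cycles * period
  t <- seq(0, duration, by = 1 / rate)
  phase <- pmax(0, t - neutral_prefix)
  wave <- 0.5 * (1 - cos(2 * pi * phase / period))
  wave[phase > cycles * period] <- 0
  theta <- outer(wave, amp)
  series <- joint_angle_series(t, theta, segment = chain$segment,
                               quantization = 0)
  q <- chain_orientation_quat(chain, theta)
  step <- global_rotation_angle(relative_rotation(q[-nrow(q), , drop = FALSE],
                                                  q[-1, , drop = FALSE]))
  if (max(step) * rate >= velocity_limit) {
    warnf("design: peak global velocity %.0f deg/s reaches the %g deg/s outlier threshold",
          max(step) * rate, velocity_limit)
  }
  series
}

#' Simulate the encoder measurement chain
#'
#' Optional backlash hysteresis (a play of `encoder_backlash` degrees: the
#' output only moves once the input has crossed the dead band) followed by
#' quantisation to the encoder grid. Deterministic.
#'
#' @param truth a ground-truth [joint_angle_series()].
#' @param noise a [noise_model()].
#' @return a [joint_angle_series()] of simulated encoder readings.
#' @export
simulate_encoders <- function(truth, noise) {
  theta <- truth$theta
  b <- noise$encoder_backlash
  if (b > 0) {
    for (j in 1:4) {
      x <- theta[, j]
      y <- numeric(length(x))
      y[1] <- x[1]
      for (i in 2:length(x)) {
        y[i] <- min(max(y[i - 1], x[i] - b / 2), x[i] + b / 2)
      }
      theta[, j] <- y
    }
  }
  q <- noise$encoder_quantization
  if (q > 0) theta <- round(theta / q) * q
  joint_angle_series(truth$t, theta, segment = truth$segment, quantization = q)
}

# Sample a truth orientation series at arbitrary times (clamped to neutral
# outside the recorded span).
sample_orientation_at <- function(series, t_query) {
  n <- length(series$t)
  tq <- pmin(pmax(t_query, series$t[1]), series$t[n])
  lo <- pmin(pmax(findInterval(tq, series$t, rightmost.closed = TRUE), 1L), n - 1L)
  hi <- lo + 1L
  u <- (tq - series$t[lo]) / (series$t[hi] - series$t[lo])
  slerp_pairs(series$q[lo, , drop = FALSE], series$q[hi, , drop = FALSE], u)
}

#' Simulate the optical reference measurement chain
#'
#' Applies the constant frame offsets, resamples the true orientation at the
#' mocap rate delayed by the inter-system lag, adds isotropic rotational
#' noise, and injects occlusion bursts concentrated where the global angle
#' is within 10% of the trial maximum. With `dropout = TRUE` a prolonged
#' loss window is injected instead, emulating a trial that must be
#' discarded. Deterministic given `seed`; the injected artefacts are
#' attached as attribute `"artifacts"`.
#'
#' @param truth_orientation ground-truth [orientation_series()] (mannequin
#'   frame).
#' @param noise a [noise_model()].
#' @param rate mocap sampling rate in Hz.
#' @param seed integer seed for noise and burst placement.
#' @param dropout inject a prolonged loss (see `noise$dropout_duration`).
#' @return an [orientation_series()] with source `"reference"`.
#' @export
simulate_mocap <- function(truth_orientation, noise, rate = 120, seed = 1,
                           dropout = FALSE) {
  t_end <- max(truth_orientation$t) + noise$time_lag
  t_m <- seq(0, t_end, by = 1 / rate)
  q_true <- sample_orientation_at(truth_orientation, t_m - noise$time_lag)
  q <- quat_multiply(quat_multiply(matrix(noise$base_offset, 1), q_true),
                     matrix(noise$sensor_offset, 1))
  n <- length(t_m)
  valid <- rep(TRUE, n)
  artifacts <- list(time_lag = noise$time_lag, bursts = list(), dropout = NULL)

  withr::with_seed(as.integer(seed), {
    if (noise$mocap_noise_sd > 0) {
      sd_c <- noise$mocap_noise_sd * DEG2RAD / sqrt(3)
      q <- quat_multiply(q, quat_from_rotvec(matrix(stats::rnorm(3 * n, 0, sd_c), ncol = 3)))
    }
    ga <- global_rotation_angle(q_true)
    if (noise$obstruction_prob_at_peak > 0 && max(ga) > 1) {
      near_peak <- ga >= 0.9 * max(ga)
      runs <- rle(near_peak)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      wb <- max(1L, round(noise$obstruction_burst * rate))
      for (k in which(runs$values)) {
        if (stats::runif(1) < noise$obstruction_prob_at_peak) {
          s0 <- starts[k] + sample.int(max(1L, runs$lengths[k]), 1) - 1L
          idx <- s0:min(n, s0 + wb - 1L)
          if (noise$obstruction_mode == "jitter") {
            jit <- quat_from_rotvec(matrix(stats::rnorm(3 * length(idx), 0,
                                                        5 * DEG2RAD), ncol = 3))
            q[idx, ] <- quat_multiply(q[idx, , drop = FALSE], jit)
          } else {
            valid[idx] <- FALSE
          }
          artifacts$bursts <- c(artifacts$bursts, list(idx))
        }
      }
    }
    if (dropout) {
      wd <- round(noise$dropout_duration * rate)
      # centred on the first motion peak so the loss hits real movement
      centre <- if (max(ga) > 1) which.max(ga) else n %/% 2
      idx <- max(1L, centre - wd %/% 2):min(n, centre + wd %/% 2)
      valid[idx] <- FALSE
      artifacts$dropout <- idx
    }
  })
  out <- orientation_series(t_m, q, valid, source = "reference", frame = "lab")
  attr(out, "artifacts") <- artifacts
  out
}

trial_id <- function(segment, condition, speed, rep) {
  sprintf("%s_%s_%s%d", segment, condition, speed, rep)
}

#' Generate a complete synthetic validation study
#'
#' Produces every measurement trial of the design plus one combined-motion
#' calibration trial per segment, together with a ground-truth ledger
#' recording the injected encoder zeros, frame offsets, lag and artefact
#' locations. Fully reproducible: the master seed fans out to per-trial
#' sub-seeds.
#'
#' @param design a [study_design()].
#' @param noise a [noise_model()].
#' @param chains named list of `dh_chain` objects (defaults to the packaged
#'   models).
#' @return a `spine_study`: `design`, `noise`, `chains`, `trials` (named
#'   list of trial records), `calibration` (per segment), `ledger`.
#' @export
generate_study <- function(design = study_design(), noise = noise_model(),
                           chains = NULL) {
  if (is.null(chains)) {
    chains <- stats::setNames(lapply(design$segments, spine_chain), design$segments)
  }
  half <- design$reps_per_condition / 2
  grid <- expand.grid(rep = seq_len(half), speed = c("fast", "slow"),
                      condition = design$conditions, segment = design$segments,
                      stringsAsFactors = FALSE)
  n_trials <- nrow(grid)
  seeds <- derive_seeds(design$seed, n_trials + 2 * length(design$segments))
  zero_seeds <- utils::tail(seeds, length(design$segments))
  enc_zero <- lapply(seq_along(design$segments), function(i) {
    withr::with_seed(zero_seeds[i], stats::rnorm(4, 0, noise$encoder_zero_sd))
  })
  names(enc_zero) <- design$segments

  make_trial <- function(segment, condition, speed, rep, sub_seed, id, calib = FALSE) {
    chain <- chains[[segment]]
    period <- if (speed == "fast") design$fast_period else design$slow_period
    amplitude <- if (speed == "fast") design$amplitude_fast else design$amplitude_slow
    truth <- generate_trajectory(chain, condition, period,
                                 cycles = design$cycles_per_trial,
                                 amplitude = amplitude,
                                 rate = design$encoder_rate,
                                 neutral_prefix = design$neutral_prefix)
    measured <- joint_angle_series(truth$t,
                                   sweep(truth$theta, 2, enc_zero[[segment]], `+`),
                                   segment = segment, quantization = 0)
    encoders <- simulate_encoders(measured, noise)
    truth_q <- orientation_series(truth$t, chain_orientation_quat(chain, truth$theta),
                                  source = "mannequin", frame = segment)
    mocap <- simulate_mocap(truth_q, noise, rate = design$mocap_rate,
                            seed = sub_seed,
                            dropout = id %in% noise$dropout_trials)
    list(id = id, segment = segment, condition = condition, speed = speed,
         rep = rep, period = period, amplitude = amplitude, seed = sub_seed,
         calibration = calib, encoders = encoders, mocap = mocap,
         truth = truth_q,
         artifacts = attr(mocap, "artifacts"))
  }

  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    g <- grid[i, ]
    id <- trial_id(g$segment, g$condition, g$speed, g$rep)
    trials[[i]] <- make_trial(g$segment, g$condition, g$speed, g$rep,
                              seeds[i], id)
  }
  names(trials) <- vapply(trials, `[[`, "", "id")
  missing_ids <- setdiff(noise$dropout_trials, names(trials))
  if (length(missing_ids)) {
    stopf("dropout_trials not in this design: %s",
          paste(missing_ids, collapse = ", "))
  }

  calib_seeds <- seeds[n_trials + seq_along(design$segments)]
  calibration <- lapply(seq_along(design$segments), function(i) {
    seg <- design$segments[i]
    make_trial(seg, "combined", "slow", 0L, calib_seeds[i],
               paste0(seg, "_calibration"), calib = TRUE)
  })
  names(calibration) <- design$segments

  ledger <- list(seed = design$seed,
                 encoder_zero = enc_zero,
                 base_offset = noise$base_offset,
                 sensor_offset = noise$sensor_offset,
                 time_lag = noise$time_lag,
                 dropout_trials = noise$dropout_trials,
                 artifacts = lapply(trials, `[[`, "artifacts"))
  structure(list(design = design, noise = noise, chains = chains,
                 trials = trials, calibration = calibration, ledger = ledger),
            class = "spine_study")
}

#' @export
print.spine_study <- function(x, ...) {
  cat(sprintf("<spine_study: %d trials (+%d calibration), segments: %s, seed %d>\n",
              length(x$trials), length(x$calibration),
              paste(x$design$segments, collapse = ", "), x$design$seed))
  invisible(x)
}
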