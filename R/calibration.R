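#' @title Cross-system calibration
#'
#' @description
#' Two constants must be identified before the encoder-driven model and the
#' optical reference can be compared: the encoder zero offsets (the mannequin
#' is zeroed in a neutral supine pose, but residual offsets survive) and the
#' constant frame misalignment between the two systems. The latter is
#' estimated from one dedicated trial per segment in which the segment is
#' moved through all three anatomical planes, by minimising the mean squared
#' relative-rotation angle between the aligned model stream and the
#' reference stream.
#'
#' @name calibration
NULL

#' Estimate encoder zero offsets from a static neutral window
#'
#' Per-channel mean of a quasi-static window. The window must be long enough
#' and still enough: channel velocities are measured over a 0.1 s stride so
#' that single-step quantization flicker does not masquerade as motion.
#'
#' @param neutral_window a [joint_angle_series()] covering the neutral pose.
#' @param max_velocity_dps stillness bound in degrees/second (default 2).
#' @param min_duration minimum window length in seconds (default 0.5).
#' @return numeric(4) zero offsets in degrees.
#' @export
zero_encoders <- function(neutral_window, max_velocity_dps = 2,
                          min_duration = 0.5) {
  t <- neutral_window$t
  if (diff(range(t)) < min_duration) {
    stopf("neutral window spans %.2f s; need at least %.2f s", diff(range(t)), min_duration)
  }
  rate <- series_rate(t)
  k <- max(1L, round(0.1 * rate))
  n <- length(t)
  if (n > k) {
    v <- (neutral_window$theta[(k + 1):n, , drop = FALSE] -
            neutral_window$theta[1:(n - k), , drop = FALSE]) /
      (t[(k + 1):n] - t[1:(n - k)])
    if (max(abs(v)) >= max_velocity_dps) {
      stopf("calibration window is not static: peak channel velocity %.1f deg/s (limit %g)",
            max(abs(v)), max_velocity_dps)
    }
  }
  colMeans(neutral_window$theta)
}

new_alignment_solution <- function(base_offset, sensor_offset, encoder_zero,
                                   residual_rmse, converged = TRUE) {
  structure(list(base_offset = drop(quat_normalize(base_offset)),
                 sensor_offset = drop(quat_normalize(sensor_offset)),
                 encoder_zero = encoder_zero,
                 residual_rmse = residual_rmse,
                 converged = converged),
            class = "alignment_solution")
}

#' @export
print.alignment_solution <- function(x, ...) {
  cat(sprintf("<alignment_solution: base %.2f deg, sensor %.2f deg, residual RMSE %.3f deg%s>\n",
              global_rotation_angle(x$base_offset),
              global_rotation_angle(x$sensor_offset),
              x$residual_rmse,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Apply an alignment solution to a model orientation stream
#'
#' @param series mannequin [orientation_series()].
#' @param solution an `alignment_solution`.
#' @return orientation series `base_offset * q * sensor_offset`.
#' @export
apply_alignment <- function(series, solution) {
  q <- quat_multiply(quat_multiply(matrix(solution$base_offset, 1), series$q),
                     matrix(solution$sensor_offset, 1))
  orientation_series(series$t, q, series$valid, source = series$source,
                     frame = series$frame)
}

alignment_cost <- function(par, q_man, q_ref, w) {
  qb <- quat_from_rotvec(par[1:3])
  qs <- quat_from_rotvec(par[4:6])
  q_pred <- quat_multiply(quat_multiply(qb, q_man), qs)
  ang <- global_rotation_angle(relative_rotation(q_pred, q_ref))
  sum(w * ang^2) / sum(w)
}

#' Estimate the constant alignment between mannequin and reference frames
#'
#' Finds two constant rotations -- one on the reference-frame side
#' (`base_offset`) and one on the body-frame side (`sensor_offset`) -- that
#' minimise the mean squared global angle between
#' `base_offset * mannequin(t) * sensor_offset` and `reference(t)` over a
#' calibration trial exciting all three anatomical planes. The cost is
#' smooth and low-dimensional; a quasi-Newton optimiser with seeded random
#' restarts makes the result deterministic and robust to local minima.
#' Optionally the four encoder zero offsets are refined jointly, in which
#' case the raw encoder series and the chain must be supplied.
#'
#' @param mannequin,reference synchronised, equal-length
#'   [orientation_series()].
#' @param refine_encoder_zero also optimise 4 encoder zero corrections.
#' @param chain,encoders required when `refine_encoder_zero = TRUE`.
#' @param zero_offsets encoder zeros already applied to `mannequin`
#'   (returned, possibly refined, in the solution).
#' @param weighting `"uniform"` (default) or `"neutral"`: the latter
#'   downweights samples far from neutral with a Gaussian kernel
#'   (`exp(-(angle/10 deg)^2)`), useful when occlusion artefacts concentrate
#'   at the amplitude extremes.
#' @param min_excitation_deg required per-plane range of motion of the
#'   calibration trial (default 5).
#' @param n_restarts seeded random restarts (default 8).
#' @param seed integer seed controlling the restarts.
#' @return an `alignment_solution`.
#' @export
align_systems <- function(mannequin, reference,
                          refine_encoder_zero = FALSE, chain = NULL,
                          encoders = NULL, zero_offsets = rep(0, 4),
                          weighting = c("uniform", "neutral"),
                          min_excitation_deg = 5, n_restarts = 8, seed = 1) {
  weighting <- match.arg(weighting)
  if (length(mannequin) != length(reference)) {
    stopf("series must be synchronised to equal length before alignment")
  }
  ok <- mannequin$valid & reference$valid
  if (sum(ok) < 10) stopf("too few valid paired samples for alignment")
  q_man0 <- mannequin$q[ok, , drop = FALSE]
  q_ref <- reference$q[ok, , drop = FALSE]

  rom <- anatomical_angles(reference)
  rom <- rom[ok, c("flexion", "lateral_flexion", "rotation")]
  plane_rom <- vapply(rom, function(x) diff(range(x)), 0)
  if (any(plane_rom < min_excitation_deg)) {
    stopf("ill-conditioned calibration: plane(s) %s move less than %g deg",
          paste(names(plane_rom)[plane_rom < min_excitation_deg], collapse = ", "),
          min_excitation_deg)
  }

  w <- if (weighting == "neutral") {
    exp(-(global_rotation_angle(q_ref) / 10)^2)
  } else rep(1, nrow(q_ref))

  refine <- isTRUE(refine_encoder_zero)
  if (refine && (is.null(chain) || is.null(encoders))) {
    stopf("refine_encoder_zero = TRUE needs both `chain` and `encoders`")
  }
  theta0 <- if (refine) sweep(encoders$theta, 2, zero_offsets, `-`)[ok, , drop = FALSE]

  cost <- function(par) {
    q_man <- if (refine) {
      chain_orientation_quat(chain, sweep(theta0, 2, par[7:10], `-`))
    } else q_man0
    alignment_cost(par[1:6], q_man, q_ref, w)
  }

  npar <- if (refine) 10L else 6L
  starts <- matrix(0, nrow = n_restarts, ncol = npar)
  if (n_restarts > 1) {
    rand <- withr::with_seed(as.integer(seed), {
      matrix(stats::runif((n_restarts - 1) * 6, -20 * DEG2RAD, 20 * DEG2RAD),
             ncol = 6)
    })
    starts[-1, 1:6] <- rand
  }

  best <- NULL
  converged <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], cost, method = "BFGS",
                        control = list(maxit = 300, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      converged <- fit$convergence == 0
    }
  }

  dzero <- if (refine) best$par[7:10] else rep(0, 4)
  new_alignment_solution(
    base_offset = quat_from_rotvec(best$par[1:3]),
    sensor_offset = quat_from_rotvec(best$par[4:6]),
    encoder_zero = zero_offsets + dzero,
    residual_rmse = sqrt(best$value),
    converged = converged)
}
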