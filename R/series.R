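#' Timestamped encoder angle series
#'
#' Container for the four revolute-joint encoder channels of one spine
#' segment. Angles are degrees; `quantization` records the encoder grid step
#' so downstream code can reason about the resolution floor.
#'
#' @param t timestamps in seconds, strictly increasing.
#' @param theta n x 4 matrix of joint angles in degrees (channels th1..th4).
#' @param segment `"cervical"` or `"lumbar"`.
#' @param quantization encoder step in degrees (NA if unknown).
#' @return a `joint_angle_series` object.
#' @export
joint_angle_series <- function(t, theta, segment = c("cervical", "lumbar"),
                               quantization = NA_real_) {
  segment <- match.arg(segment)
  theta <- as.matrix(theta)
  if (ncol(theta) != 4) {
    stopf("encoder series must have exactly 4 channels, got %d", ncol(theta))
  }
  if (length(t) != nrow(theta)) stopf("timestamps and angles disagree in length")
  if (length(t) > 1 && any(diff(t) <= 0)) stopf("timestamps must be strictly increasing")
  colnames(theta) <- paste0("th", 1:4)
  structure(list(t = as.numeric(t), theta = theta, segment = segment,
                 quantization = quantization),
            class = "joint_angle_series")
}

#' Timestamped orientation series
#'
#' Unit-quaternion orientation of one rigid body relative to a reference
#' frame, with a per-sample validity mask (mocap samples lost to marker
#' occlusion are carried as invalid rather than dropped, so timestamps stay
#' regular).
#'
#' @param t timestamps in seconds, strictly increasing.
#' @param q n x 4 quaternion matrix (scalar first); normalised on input.
#' @param valid logical mask, default all TRUE.
#' @param source `"mannequin"` or `"reference"`.
#' @param frame free-text reference-frame identifier.
#' @return an `orientation_series` object.
#' @export
orientation_series <- function(t, q, valid = NULL,
                               source = c("mannequin", "reference"),
                               frame = "base") {
  source <- match.arg(source)
  q <- as_quat(q)
  if (length(t) != nrow(q)) stopf("timestamps and quaternions disagree in length")
  if (length(t) > 1 && any(diff(t) <= 0)) stopf("timestamps must be strictly increasing")
  if (is.null(valid)) valid <- rep(TRUE, length(t))
  if (length(valid) != length(t)) stopf("validity mask must match series length")
  if (any(valid)) q[valid, ] <- quat_normalize(q[valid, , drop = FALSE])
  colnames(q) <- c("qw", "qx", "qy", "qz")
  structure(list(t = as.numeric(t), q = q, valid = as.logical(valid),
                 source = source, frame = frame),
            class = "orientation_series")
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("<joint_angle_series: %s, %d samples, %.2f s, quantization %s deg>\n",
              x$segment, length(x$t), diff(range(x$t)),
              format(x$quantization)))
  invisible(x)
}

#' @export
print.orientation_series <- function(x, ...) {
  cat(sprintf("<orientation_series: %s in frame '%s', %d samples (%d valid), %.2f s>\n",
              x$source, x$frame, length(x$t), sum(x$valid), diff(range(x$t))))
  invisible(x)
}

#' @export
length.orientation_series <- function(x) length(x$t)

#' @export
length.joint_angle_series <- function(x) length(x$t)

series_rate <- function(t) {
  if (length(t) < 2) return(NA_real_)
  1 / stats::median(diff(t))
}

#' Anatomical angle traces of an orientation series
#'
#' Convenience wrapper: decomposes every sample and appends the global
#' rotation angle column.
#'
#' @param series an `orientation_series`.
#' @param convention an [anatomical_convention()].
#' @return data.frame with `t`, `global`, `flexion`, `lateral_flexion`,
#'   `rotation`, `degenerate`, `valid`.
#' @export
anatomical_angles <- function(series, convention = anatomical_convention()) {
  ang <- decompose_anatomical(series$q, convention)
  data.frame(t = series$t, global = global_rotation_angle(series$q),
             ang[, c("flexion", "lateral_flexion", "rotation")],
             degenerate = ang$degenerate, valid = series$valid)
}
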