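#' @title Rotation primitives: quaternions, matrices and anatomical angles
#'
#' @description
#' All orientation handling in spineval is built on three representations:
#' rotation matrices (3x3, proper orthogonal), unit quaternions
#' (scalar-first, canonicalised to `w >= 0`), and anatomical angles
#' (flexion / lateral flexion / axial rotation, an intrinsic Tait-Bryan
#' decomposition about configurable body axes). Quaternion series are stored
#' as n x 4 numeric matrices with columns `w, x, y, z`; every function here
#' is vectorised over rows. Angles are radians internally and degrees at the
#' API boundary.
#'
#' @name rotation-core
NULL

as_quat <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  if (ncol(q) != 4) stopf("a quaternion needs 4 components (w, x, y, z), got %d", ncol(q))
  q
}

#' Normalise and canonicalise quaternions
#'
#' Scales each quaternion to unit norm and flips its sign so the scalar part
#' is non-negative. The sign flip removes the double-cover ambiguity: `q` and
#' `-q` encode the same rotation, so comparisons are done on the `w >= 0`
#' hemisphere.
#'
#' @param q quaternion (length-4 vector or n x 4 matrix, scalar first).
#' @return matrix of unit quaternions with `w >= 0`.
#' @export
quat_normalize <- function(q) {
  q <- as_quat(q)
  nrm <- sqrt(rowSums(q^2))
  if (any(nrm < 1e-12)) stopf("zero-norm quaternion is not a rotation")
  q <- q / nrm
  flip <- q[, 1] < 0
  q[flip, ] <- -q[flip, , drop = FALSE]
  q
}

#' Hamilton product of quaternion series
#'
#' @param a,b quaternions (vectors or n x 4 matrices; recycled row-wise if
#'   one side has a single row).
#' @param canonical flip results onto the `w >= 0` hemisphere (default TRUE).
#' @return n x 4 matrix `a %*% b` in the Hamilton sense (apply `b` first when
#'   quaternions act by `R(a) R(b)`).
#' @export
quat_multiply <- function(a, b, canonical = TRUE) {
  a <- as_quat(a); b <- as_quat(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), , drop = FALSE]
  if (nrow(b) == 1 && n > 1) b <- b[rep(1, n), , drop = FALSE]
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  out <- cbind(w = w, x = x, y = y, z = z)
  if (canonical) {
    flip <- out[, 1] < 0
    out[flip, ] <- -out[flip, , drop = FALSE]
  }
  out
}

#' @rdname quat_multiply
#' @export
quat_conjugate <- function(a) {
  a <- as_quat(a)
  cbind(w = a[, 1], x = -a[, 2], y = -a[, 3], z = -a[, 4])
}

#' Quaternion from axis and angle
#'
#' @param axis length-3 axis (need not be unit).
#' @param angle_deg rotation angle in degrees (vectorised).
#' @return n x 4 unit quaternion matrix.
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  half <- angle_deg * DEG2RAD / 2
  quat_normalize(cbind(cos(half), sin(half) * axis[1], sin(half) * axis[2],
                       sin(half) * axis[3]))
}

# Rotation-vector (axis * angle, radians) <-> quaternion, vectorised.
quat_from_rotvec <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  ang <- sqrt(rowSums(v^2))
  half <- ang / 2
  # sinc(half): series near zero keeps this smooth for the optimiser
  s <- ifelse(ang < 1e-8, 0.5 - ang^2 / 48, sin(half) / ang)
  quat_normalize(cbind(cos(half), v[, 1] * s, v[, 2] * s, v[, 3] * s))
}

check_rotation_matrix <- function(R, tol = 1e-8) {
  if (!is.matrix(R) || any(dim(R) != c(3, 3))) {
    stopf("a rotation must be a 3x3 matrix")
  }
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    stopf("matrix is not a proper rotation (orthonormality/determinant tolerance %g)", tol)
  }
  invisible(R)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Uses Shepperd's method (largest diagonal pivot) for numerical stability
#' across the whole rotation group; the result lies on the `w >= 0`
#' hemisphere.
#'
#' @param R 3x3 proper orthogonal matrix.
#' @param tol orthonormality tolerance for input validation.
#' @return length-4 unit quaternion `(w, x, y, z)`.
#' @export
matrix_to_quaternion <- function(R, tol = 1e-8) {
  check_rotation_matrix(R, tol)
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > max(R[1, 1], R[2, 2], R[3, 3])) {
    s <- 2 * sqrt(1 + tr)
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- 2 * sqrt(1 + R[i, i] - R[j, j] - R[k, k])
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  drop(quat_normalize(q))
}

#' Convert unit quaternions to rotation matrices
#'
#' @param q quaternion (vector for a single rotation; matrix input returns a
#'   3 x 3 x n array).
#' @return 3x3 matrix, or 3 x 3 x n array for series input.
#' @export
quaternion_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  els <- cbind(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
               2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
               2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2))
  if (nrow(q) == 1) return(matrix(els[1, ], 3, 3))
  array(t(els), dim = c(3, 3, nrow(q)))
}

#' Global rotation angle of a quaternion
#'
#' The magnitude of the single rotation a quaternion encodes,
#' `2 * acos(|w|)`, in degrees. It is independent of the rotation axis and
#' of the quaternion's sign, which makes it an axis-free range-of-motion
#' score for spine segments.
#'
#' @param q quaternion (vector or n x 4 matrix).
#' @return numeric vector of angles in `[0, 180]` degrees.
#' @export
global_rotation_angle <- function(q) {
  q <- quat_normalize(q)
  2 * acos(clamp1(abs(q[, 1]))) * RAD2DEG
}

#' Relative rotation between two orientations
#'
#' Returns `r` such that `q_a` composed with `r` reproduces `q_b`
#' (`q_a %*% r = q_b`), i.e. the rotation taking frame `a` onto frame `b`.
#'
#' @param q_a,q_b unit quaternions (vectors or aligned n x 4 matrices).
#' @return n x 4 quaternion matrix.
#' @export
relative_rotation <- function(q_a, q_b) {
  quat_multiply(quat_conjugate(quat_normalize(q_a)), quat_normalize(q_b))
}

#' Spherical linear interpolation
#'
#' Geodesic interpolation between two orientations along the shortest arc;
#' the rotation angle from `q_a` to the result grows linearly in `t`.
#'
#' @param q_a,q_b unit quaternions (length-4 vectors).
#' @param t interpolation fractions in `[0, 1]` (vectorised).
#' @return length(t) x 4 quaternion matrix.
#' @export
quat_slerp <- function(q_a, q_b, t) {
  qa <- drop(quat_normalize(q_a)); qb <- drop(quat_normalize(q_b))
  d <- sum(qa * qb)
  if (d < 0) { qb <- -qb; d <- -d }   # shortest arc
  d <- clamp1(d)
  if (d > 1 - 1e-10) {
    out <- outer(1 - t, qa) + outer(t, qb)   # nearly parallel: nlerp
  } else {
    om <- acos(d)
    out <- outer(sin((1 - t) * om) / sin(om), qa) +
      outer(sin(t * om) / sin(om), qb)
  }
  quat_normalize(out)
}

# ---- anatomical (Tait-Bryan) decomposition -------------------------------

AXIS_INDEX <- c(x = 1L, y = 2L, z = 3L)
CYCLIC_SEQS <- c("xyz", "yzx", "zxy")

parse_signed_axis <- function(ax) {
  sgn <- 1
  if (startsWith(ax, "-")) { sgn <- -1; ax <- substring(ax, 2) }
  if (!ax %in% names(AXIS_INDEX)) stopf("unknown axis '%s'", ax)
  list(axis = ax, sign = sgn)
}

#' Anatomical decomposition convention
#'
#' Declares which body axis carries each anatomical plane and the intrinsic
#' order in which the three elemental rotations are applied. The default
#' (flexion about `-y`, lateral flexion about `x`, axial rotation about `z`,
#' applied flexion -> lateral flexion -> rotation) matches the joint axes of
#' the packaged spine models; both the axes and the order are configuration,
#' not constants, because reporting conventions differ between laboratories.
#'
#' @param flexion,lateral_flexion,rotation signed axis labels
#'   (`"x"`, `"-y"`, ...). The three unsigned axes must be distinct.
#' @param order character vector giving the intrinsic application order of
#'   the three planes.
#' @return an `anatomical_convention` object.
#' @export
anatomical_convention <- function(flexion = "-y", lateral_flexion = "x",
                                  rotation = "z",
                                  order = c("flexion", "lateral_flexion", "rotation")) {
  planes <- list(flexion = parse_signed_axis(flexion),
                 lateral_flexion = parse_signed_axis(lateral_flexion),
                 rotation = parse_signed_axis(rotation))
  axes <- vapply(planes, `[[`, "", "axis")
  if (anyDuplicated(axes)) {
    stopf("anatomical planes must use three distinct axes (got %s)",
          paste(axes, collapse = ", "))
  }
  if (!setequal(order, names(planes)) || length(order) != 3) {
    stopf("order must be a permutation of flexion, lateral_flexion, rotation")
  }
  structure(list(planes = planes, order = order), class = "anatomical_convention")
}

# Vectorised intrinsic Tait-Bryan angles from quaternion rows.
# seq: 3-letter axis string with distinct letters. Returns radians (n x 3)
# with a "gimbal" attribute flagging rows inside the guard band.
euler_from_quat <- function(q, seq, guard_deg = 0.5) {
  q <- quat_normalize(q)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  # full element set of R(q); picked into by axis indices below
  R <- list(
    cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    cbind(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    cbind(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
  el <- function(i, j) R[[i]][, j]
  ax <- AXIS_INDEX[strsplit(seq, "")[[1]]]
  if (length(ax) != 3 || anyDuplicated(ax)) {
    stopf("sequence must be three distinct axes, got '%s'", seq)
  }
  i <- ax[1]; j <- ax[2]; k <- ax[3]
  eps <- if (seq %in% CYCLIC_SEQS) 1 else -1
  s2 <- clamp1(eps * el(i, k))
  t2 <- asin(s2)
  gimbal <- abs(abs(t2) - pi / 2) < guard_deg * DEG2RAD
  t1 <- atan2(-eps * el(j, k), el(k, k))
  t3 <- atan2(-eps * el(i, j), el(i, i))
  if (any(gimbal)) {
    # degenerate: first and third axes align; put the whole remaining
    # rotation on the first angle and zero the third
    gsign <- sign(s2[gimbal])
    t1[gimbal] <- atan2(gsign * eps * el(j, i)[gimbal], el(j, j)[gimbal])
    t3[gimbal] <- 0
  }
  out <- cbind(t1, t2, t3)
  attr(out, "gimbal") <- gimbal
  out
}

euler_to_quat <- function(angles_rad, seq) {
  if (is.null(dim(angles_rad))) angles_rad <- matrix(angles_rad, nrow = 1)
  axes <- strsplit(seq, "")[[1]]
  q <- NULL
  for (s in 1:3) {
    unit <- c(0, 0, 0); unit[AXIS_INDEX[axes[s]]] <- 1
    half <- angles_rad[, s] / 2
    qs <- cbind(cos(half), sin(half) %o% unit)
    q <- if (is.null(q)) qs else quat_multiply(q, qs, canonical = FALSE)
  }
  quat_normalize(q)
}

#' Decompose an orientation into anatomical angles
#'
#' Splits a rotation into the three clinically named elemental rotations
#' (flexion, lateral flexion, axial rotation) applied intrinsically in the
#' convention's order. Inside the gimbal-lock guard band (middle angle within
#' `guard_deg` of +/-90 degrees) the split is degenerate; affected samples
#' are flagged rather than silently resolved.
#'
#' @param x a 3x3 rotation matrix, a length-4 quaternion, or an n x 4
#'   quaternion matrix.
#' @param convention an [anatomical_convention()].
#' @param guard_deg half-width of the gimbal guard band in degrees.
#' @return data.frame with columns `flexion`, `lateral_flexion`, `rotation`
#'   (degrees, in `(-180, 180]`) and logical `degenerate`.
#' @export
decompose_anatomical <- function(x, convention = anatomical_convention(),
                                 guard_deg = 0.5) {
  if (is.matrix(x) && all(dim(x) == c(3, 3))) {
    q <- matrix(matrix_to_quaternion(x), nrow = 1)
  } else {
    q <- quat_normalize(x)
  }
  ord <- convention$order
  seq <- paste(vapply(convention$planes[ord], `[[`, "", "axis"), collapse = "")
  ang <- euler_from_quat(q, seq, guard_deg)
  signs <- vapply(convention$planes[ord], `[[`, 1, "sign")
  out <- sweep(ang, 2, signs, `*`) * RAD2DEG
  colnames(out) <- ord
  out <- as.data.frame(out)[, c("flexion", "lateral_flexion", "rotation")]
  out$degenerate <- attr(ang, "gimbal")
  out
}

#' Recompose anatomical angles into a quaternion
#'
#' Inverse of [decompose_anatomical()] outside the gimbal guard band.
#'
#' @param flexion,lateral_flexion,rotation angles in degrees (vectorised).
#' @param convention an [anatomical_convention()].
#' @return n x 4 unit quaternion matrix.
#' @export
recompose_anatomical <- function(flexion, lateral_flexion, rotation,
                                 convention = anatomical_convention()) {
  ang <- cbind(flexion = flexion, lateral_flexion = lateral_flexion,
               rotation = rotation)
  ord <- convention$order
  seq <- paste(vapply(convention$planes[ord], `[[`, "", "axis"), collapse = "")
  signs <- vapply(convention$planes[ord], `[[`, 1, "sign")
  euler_to_quat(sweep(ang[, ord, drop = FALSE], 2, signs, `*`) * DEG2RAD, seq)
}
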