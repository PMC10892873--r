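#' @title Denavit-Hartenberg spine models
#'
#' @description
#' The mannequin's cervical and lumbar segments are serial chains of four
#' revolute joints (two flexion, one lateral flexion, one axial rotation)
#' described in the Denavit-Hartenberg convention: each link carries four
#' parameters (a: link length, alpha: link twist, d: link offset,
#' theta: joint angle), and the link-to-link transform is
#' `T = Rz(theta) Rx(alpha)` with translation `(a cos(theta), a sin(theta), d)`.
#' The chain product gives the end effector (head or trunk) relative to the
#' base (trunk or pelvis). Both packaged chains are arranged so that the
#' all-zero joint configuration yields the identity orientation: the final
#' virtual frame of the cervical chain exists purely to align the
#' end-effector frame with the base in the neutral pose.
#'
#' @name spine-model
NULL

eval_length <- function(x, link_lengths) {
  if (is.numeric(x)) return(x)
  e <- list2env(as.list(link_lengths))
  v <- try(eval(parse(text = x), envir = e, enclos = baseenv()), silent = TRUE)
  if (inherits(v, "try-error") || !is.numeric(v)) {
    stopf("cannot resolve link-length expression '%s'", x)
  }
  v
}

#' One Denavit-Hartenberg parameter row
#'
#' @param a link length (length units; may be an expression in the chain's
#'   link lengths, e.g. `"r2+r3"`).
#' @param alpha_deg link twist in degrees.
#' @param d link offset (length units or expression).
#' @param theta_offset_deg constant joint-angle offset in degrees.
#' @param joint_index encoder channel (1-4) driving this row, or `"fixed"`
#'   for a constant virtual frame.
#' @param plane anatomical plane this joint actuates
#'   (`"flexion"`, `"lateral_flexion"`, `"rotation"`, or NA for fixed rows).
#' @return a `dh_row` list.
#' @export
dh_row <- function(a = 0, alpha_deg = 0, d = 0, theta_offset_deg = 0,
                   joint_index = "fixed", plane = NA_character_) {
  if (!identical(joint_index, "fixed")) {
    joint_index <- as.integer(joint_index)
    if (!joint_index %in% 1:4) stopf("joint_index must be 1..4 or 'fixed'")
  }
  structure(list(a = a, alpha = alpha_deg * DEG2RAD, d = d,
                 theta_offset = theta_offset_deg * DEG2RAD,
                 joint_index = joint_index, plane = plane),
            class = "dh_row")
}

#' Assemble a spine segment kinematic chain
#'
#' @param segment `"cervical"` or `"lumbar"`.
#' @param rows list of [dh_row()] in base-to-end order.
#' @param link_lengths named numeric vector `r1, r2, r3`. The paper-style
#'   analysis validates orientation only, which is analytically independent
#'   of these lengths; they default to 1 unit.
#' @param convention the [anatomical_convention()] used when decomposing
#'   this chain's output.
#' @param joint_limits_deg symmetric joint limit used for range warnings.
#' @return a `dh_chain` object.
#' @export
dh_chain <- function(segment = c("cervical", "lumbar"), rows,
                     link_lengths = c(r1 = 1, r2 = 1, r3 = 1),
                     convention = anatomical_convention(),
                     joint_limits_deg = 90) {
  segment <- match.arg(segment)
  if (!all(vapply(rows, inherits, TRUE, "dh_row"))) {
    stopf("rows must be a list of dh_row objects")
  }
  actuated <- vapply(rows, function(r) !identical(r$joint_index, "fixed"), TRUE)
  idx <- sort(unlist(lapply(rows[actuated], `[[`, "joint_index")))
  if (!identical(as.integer(idx), 1:4)) {
    stopf("chain must actuate each encoder channel 1..4 exactly once")
  }
  structure(list(segment = segment, rows = rows, link_lengths = link_lengths,
                 convention = convention, joint_limits_deg = joint_limits_deg),
            class = "dh_chain")
}

#' @export
print.dh_chain <- function(x, ...) {
  cat(sprintf("<dh_chain: %s, %d rows (%d actuated)>\n", x$segment,
              length(x$rows),
              sum(vapply(x$rows, function(r) !identical(r$joint_index, "fixed"), TRUE))))
  invisible(x)
}

#' Load a spine chain from a YAML description
#'
#' The file mirrors the model parameter table: a list of joints with keys
#' `a`, `alpha_deg`, `d`, `theta_offset_deg`, `joint_index`, `plane`, plus
#' `segment` and `link_lengths`. The two shipped models live under
#' `system.file("extdata/chains", package = "spineval")`.
#'
#' @param path YAML file path.
#' @return a `dh_chain`.
#' @export
read_chain_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  conv <- if (is.null(cfg$convention)) anatomical_convention() else {
    do.call(anatomical_convention, cfg$convention)
  }
  rows <- lapply(cfg$joints, function(j) {
    dh_row(a = j$a %||% 0, alpha_deg = j$alpha_deg %||% 0, d = j$d %||% 0,
           theta_offset_deg = j$theta_offset_deg %||% 0,
           joint_index = j$joint_index %||% "fixed",
           plane = j$plane %||% NA_character_)
  })
  ll <- unlist(cfg$link_lengths %||% c(r1 = 1, r2 = 1, r3 = 1))
  dh_chain(segment = cfg$segment, rows = rows, link_lengths = ll,
           convention = conv,
           joint_limits_deg = cfg$joint_limits_deg %||% 90)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The packaged spine segment models
#'
#' @param segment `"cervical"` (5 rows: 4 actuated + 1 fixed virtual frame)
#'   or `"lumbar"` (4 actuated rows).
#' @param link_lengths optional override of `r1, r2, r3`.
#' @return a `dh_chain`.
#' @export
spine_chain <- function(segment = c("cervical", "lumbar"), link_lengths = NULL) {
  segment <- match.arg(segment)
  path <- system.file("extdata", "chains", paste0(segment, ".yaml"),
                      package = "spineval", mustWork = TRUE)
  chain <- read_chain_config(path)
  if (!is.null(link_lengths)) chain$link_lengths[names(link_lengths)] <- link_lengths
  chain
}

#' Single-link Denavit-Hartenberg transform
#'
#' @param row a [dh_row()].
#' @param theta_deg encoder angle in degrees (ignored for fixed rows).
#' @param link_lengths named lengths used to resolve symbolic `a`/`d`.
#' @return 4x4 homogeneous transform.
#' @export
dh_transform <- function(row, theta_deg = 0,
                         link_lengths = c(r1 = 1, r2 = 1, r3 = 1)) {
  th <- row$theta_offset + if (identical(row$joint_index, "fixed")) 0 else theta_deg * DEG2RAD
  a <- eval_length(row$a, link_lengths)
  d <- eval_length(row$d, link_lengths)
  ct <- cos(th); st <- sin(th); ca <- cos(row$alpha); sa <- sin(row$alpha)
  rbind(c(ct, -st * ca,  st * sa, a * ct),
        c(st,  ct * ca, -ct * sa, a * st),
        c(0,        sa,       ca,      d),
        c(0,         0,        0,      1))
}

chain_thetas <- function(chain, theta_deg) {
  vapply(chain$rows, function(r) {
    if (identical(r$joint_index, "fixed")) 0 else theta_deg[r$joint_index]
  }, 0)
}

#' Forward kinematics of a spine chain
#'
#' Product of the per-row transforms in base-to-end order; the rotation
#' block is the orientation of the end effector relative to the base.
#'
#' @param chain a `dh_chain`.
#' @param theta_deg numeric(4) encoder angles in degrees.
#' @param warn_limits warn when an angle exceeds the configured joint limit.
#' @return 4x4 homogeneous transform.
#' @export
forward_kinematics <- function(chain, theta_deg, warn_limits = TRUE) {
  if (length(theta_deg) != 4) stopf("forward kinematics needs 4 joint angles")
  if (warn_limits && any(abs(theta_deg) > chain$joint_limits_deg)) {
    warnf("joint angle outside the configured +/-%g deg range", chain$joint_limits_deg)
  }
  per_row <- chain_thetas(chain, theta_deg)
  T <- diag(4)
  for (i in seq_along(chain$rows)) {
    T <- T %*% dh_transform(chain$rows[[i]], per_row[i], chain$link_lengths)
  }
  T
}

# Orientation-only chain product, vectorised over samples via quaternions:
# each row's rotation Rz(theta') Rx(alpha) is qz(theta') * qx(alpha).
chain_orientation_quat <- function(chain, theta_deg) {
  theta_deg <- as.matrix(theta_deg)
  n <- nrow(theta_deg)
  q <- matrix(rep(c(1, 0, 0, 0), n), ncol = 4, byrow = TRUE)
  for (row in chain$rows) {
    th <- row$theta_offset +
      if (identical(row$joint_index, "fixed")) 0 else theta_deg[, row$joint_index] * DEG2RAD
    half_t <- th / 2
    qrow <- quat_multiply(cbind(cos(half_t), 0, 0, sin(half_t)),
                          matrix(c(cos(row$alpha / 2), sin(row$alpha / 2), 0, 0),
                                 nrow = 1),
                          canonical = FALSE)
    q <- quat_multiply(q, qrow, canonical = FALSE)
  }
  quat_normalize(q)
}

#' Encoder series to anatomical orientation series
#'
#' Applies forward kinematics sample by sample to zeroed encoder angles,
#' producing the end-effector-relative-to-base orientation stream.
#'
#' @param chain a `dh_chain` for the series' segment.
#' @param series a [joint_angle_series()].
#' @param zero_offsets numeric(4), degrees, from [zero_encoders()]
#'   (all-zero allowed).
#' @return an [orientation_series()] with source `"mannequin"`.
#' @export
encoder_series_to_orientation <- function(chain, series, zero_offsets = rep(0, 4)) {
  if (!inherits(series, "joint_angle_series")) stopf("series must be a joint_angle_series")
  if (length(zero_offsets) != 4) stopf("zero_offsets must have 4 entries")
  theta <- sweep(series$theta, 2, zero_offsets, `-`)
  q <- chain_orientation_quat(chain, theta)
  orientation_series(series$t, q, source = "mannequin", frame = chain$segment)
}
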