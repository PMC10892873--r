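#' @title Stream preprocessing: resampling, synchronisation, outlier repair
#'
#' @description
#' The two measurement systems run on independent clocks and rates, and the
#' optical reference is momentarily unreliable when markers are obstructed.
#' Preprocessing therefore (1) resamples both orientation streams to a
#' common uniform rate, (2) estimates the inter-system lag by normalised
#' cross-correlation on the anatomical-angle channel with the greatest range
#' of motion (each trial keeps one second of neutral pose before movement
#' onset, which anchors the correlation), (3) flags samples whose
#' instantaneous global angular velocity exceeds a threshold (default
#' 120 deg/s) as implausible for the mannequin's motion, and (4) repairs
#' flagged samples by spherical interpolation when fewer than half the
#' samples in a 0.2 s window are flagged, leaving denser corruption invalid.
#'
#' @name preprocessing
NULL

# Row-paired slerp: interpolate q_a[i] -> q_b[i] by fraction u[i].
slerp_pairs <- function(qa, qb, u) {
  d <- rowSums(qa * qb)
  qb[d < 0, ] <- -qb[d < 0, , drop = FALSE]
  d <- clamp1(abs(d))
  om <- acos(d)
  near <- om < 1e-6
  wa <- ifelse(near, 1 - u, sin((1 - u) * om) / sin(pmax(om, 1e-12)))
  wb <- ifelse(near, u, sin(u * om) / sin(pmax(om, 1e-12)))
  quat_normalize(qa * wa + qb * wb)
}

#' Resample an orientation series to a uniform rate
#'
#' Quaternions are interpolated along geodesics (slerp); a resampled point
#' is valid only when both bracketing source samples are valid (exact grid
#' hits inherit the validity of the hit sample).
#'
#' @param series an [orientation_series()].
#' @param rate target rate in Hz.
#' @return a uniformly sampled [orientation_series()].
#' @export
resample_orientation <- function(series, rate) {
  if (rate <= 0) stopf("rate must be positive")
  n <- length(series$t)
  if (n < 2) stopf("cannot resample a series with fewer than 2 samples")
  t_new <- seq(series$t[1], series$t[n], by = 1 / rate)
  lo <- findInterval(t_new, series$t, rightmost.closed = TRUE)
  lo <- pmin(pmax(lo, 1L), n - 1L)
  hi <- lo + 1L
  u <- (t_new - series$t[lo]) / (series$t[hi] - series$t[lo])
  q <- slerp_pairs(series$q[lo, , drop = FALSE], series$q[hi, , drop = FALSE], u)
  eps <- 1e-9
  valid <- ifelse(u < eps, series$valid[lo],
                  ifelse(u > 1 - eps, series$valid[hi],
                         series$valid[lo] & series$valid[hi]))
  orientation_series(t_new, q, as.logical(valid), source = series$source,
                     frame = series$frame)
}

#' Estimate the inter-system lag by cross-correlation
#'
#' Both series must already share a common uniform rate. The anatomical
#' channel (flexion, lateral flexion or rotation) with the greatest range of
#' motion in `a` is selected, both channel signals are mean-removed, and the
#' normalised cross-correlation is evaluated at every integer-sample shift
#' within `max_lag`. A positive lag means `b` is delayed relative to `a`.
#'
#' @param a,b [orientation_series()] at a common rate.
#' @param max_lag search half-window in seconds (default 2).
#' @param convention decomposition convention for the channel signals.
#' @param min_rom minimum usable range of motion in degrees (default 1).
#' @param require_neutral_prefix enforce that each series starts with at
#'   least one second of quasi-neutral data (max global angle
#'   `neutral_tol_deg` over the first second).
#' @param neutral_tol_deg quasi-neutral bound in degrees (default 5).
#' @return a `sync_result`: `lag` (s), `lag_samples`, `peak_correlation`,
#'   `channel_used`.
#' @export
synchronize <- function(a, b, max_lag = 2,
                        convention = anatomical_convention(), min_rom = 1,
                        require_neutral_prefix = TRUE, neutral_tol_deg = 5) {
  rate_a <- series_rate(a$t); rate_b <- series_rate(b$t)
  if (abs(rate_a - rate_b) > 1e-6 * rate_a) {
    stopf("series must be resampled to a common rate before synchronisation")
  }
  if (require_neutral_prefix) {
    for (s in list(a, b)) {
      pre <- which(s$valid & (s$t - s$t[1] <= 1))
      if (length(pre) > 1) {
        # quasi-neutral = still: rotation relative to the prefix start
        dev <- global_rotation_angle(relative_rotation(
          s$q[pre[1], , drop = FALSE], s$q[pre, , drop = FALSE]))
        if (max(dev) > neutral_tol_deg) {
          stopf("series does not start with 1 s of quasi-neutral data (> %g deg of motion)",
                neutral_tol_deg)
        }
      }
    }
  }
  ang_a <- anatomical_angles(a, convention)
  ang_b <- anatomical_angles(b, convention)
  planes <- c("flexion", "lateral_flexion", "rotation")
  rom <- vapply(planes, function(p) diff(range(ang_a[[p]][a$valid])), 0)
  if (max(rom) < min_rom) {
    stopf("unsynchronizable: largest plane range of motion %.2f deg < %g deg",
          max(rom), min_rom)
  }
  channel <- planes[which.max(rom)]
  sa <- ang_a[[channel]]; sa[!a$valid] <- NA
  sb <- ang_b[[channel]]; sb[!b$valid] <- NA
  L <- round(max_lag * rate_a)
  shifts <- (-L):L
  cc <- vapply(shifts, function(s) {
    # pair a[i] with b[i + s]
    ia <- seq_len(length(sa))
    ib <- ia + s
    keep <- ib >= 1 & ib <= length(sb)
    x <- sa[ia[keep]]; y <- sb[ib[keep]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 10) return(NA_real_)
    suppressWarnings(stats::cor(x[ok], y[ok]))
  }, 0)
  if (all(is.na(cc))) stopf("unsynchronizable: no overlapping valid samples")
  best <- which.max(cc)
  structure(list(lag_samples = shifts[best], lag = shifts[best] / rate_a,
                 peak_correlation = cc[best], channel_used = channel),
            class = "sync_result")
}

#' Align two series using a sync result
#'
#' Pairs `a[i]` with `b[i + lag_samples]` and trims both series to the
#' overlap, putting `b` on `a`'s timestamps.
#'
#' @param a,b the series passed to [synchronize()].
#' @param sync a `sync_result`.
#' @return list with elements `a` and `b`, equal-length aligned series.
#' @export
apply_sync <- function(a, b, sync) {
  s <- sync$lag_samples
  ia <- seq_len(length(a$t))
  ib <- ia + s
  keep <- ib >= 1 & ib <= length(b$t)
  ia <- ia[keep]; ib <- ib[keep]
  list(a = orientation_series(a$t[ia], a$q[ia, , drop = FALSE], a$valid[ia],
                              source = a$source, frame = a$frame),
       b = orientation_series(a$t[ia], b$q[ib, , drop = FALSE], b$valid[ib],
                              source = b$source, frame = b$frame))
}

#' Flag implausible high-velocity samples
#'
#' Instantaneous global angular velocity is the relative-rotation angle
#' between consecutive samples divided by the time step; both samples
#' bounding a step above the threshold are flagged. Marker obstruction in
#' optical systems shows up as exactly this kind of teleporting jitter.
#'
#' @param series a uniformly sampled [orientation_series()].
#' @param velocity_threshold degrees/second (default 120).
#' @return logical mask, TRUE where flagged.
#' @export
detect_outliers <- function(series, velocity_threshold = 120) {
  n <- length(series$t)
  mask <- rep(FALSE, n)
  if (n < 2) return(mask)
  step <- global_rotation_angle(
    relative_rotation(series$q[-n, , drop = FALSE], series$q[-1, , drop = FALSE]))
  v <- step / diff(series$t)
  bad <- which(v > velocity_threshold)
  mask[bad] <- TRUE       # left sample of each offending step
  mask[bad + 1L] <- TRUE  # right sample
  mask
}

#' Repair flagged samples by spherical interpolation
#'
#' Sliding 0.2 s windows (50% overlap) are examined: a flagged sample that
#' falls in at least one window with fewer than 50% flagged samples is
#' replaced by slerp between its nearest clean neighbours and marked valid;
#' samples only covered by denser corruption stay invalid and are excluded
#' downstream. Timestamps are never altered.
#'
#' @param series a uniformly sampled [orientation_series()].
#' @param mask logical flag mask aligned with the series (e.g. from
#'   [detect_outliers()], optionally OR-ed with `!series$valid`).
#' @param window window length in seconds (default 0.2).
#' @return a repaired [orientation_series()].
#' @export
repair_series <- function(series, mask, window = 0.2) {
  n <- length(series$t)
  if (length(mask) != n) stopf("mask must align with the series")
  if (all(mask)) {
    stop(structure(class = c("spineval_irreparable", "error", "condition"),
                   list(message = "irreparable trial: every sample is flagged",
                        call = NULL)))
  }
  if (!any(mask)) return(series)
  rate <- series_rate(series$t)
  w <- max(2L, round(window * rate))
  hop <- max(1L, w %/% 2L)
  starts <- unique(c(seq(1L, max(1L, n - w + 1L), by = hop), n - w + 1L))
  repairable <- rep(FALSE, n)
  for (s in starts) {
    idx <- s:min(n, s + w - 1L)
    if (mean(mask[idx]) < 0.5) repairable[idx] <- TRUE
  }
  repairable <- repairable & mask

  clean <- which(!mask & series$valid)
  q <- series$q
  valid <- series$valid & !mask
  for (i in which(repairable)) {
    left <- clean[clean < i]
    right <- clean[clean > i]
    if (!length(left) || !length(right)) next   # edge: no bracketing data
    l <- max(left); r <- min(right)
    u <- (series$t[i] - series$t[l]) / (series$t[r] - series$t[l])
    q[i, ] <- quat_slerp(series$q[l, ], series$q[r, ], u)
    valid[i] <- TRUE
  }
  orientation_series(series$t, q, valid, source = series$source,
                     frame = series$frame)
}
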