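#' @title End-to-end validation pipeline
#'
#' @description
#' Orchestrates the whole concurrent-validity analysis over a study:
#' per segment, encoder zeroing and frame alignment are estimated from the
#' calibration trial, every measurement trial is converted to anatomical
#' orientation, synchronised, cleaned, and compared to the reference, and
#' the agreement statistics are aggregated into the report tables (RMSE per
#' plane, Bland-Altman per plane, reliability/SEM/MDC per plane,
#' non-inferiority per segment). Trials whose reference stream cannot be
#' repaired are discarded with an explicit reason, never silently dropped.
#'
#' @name pipeline
NULL

#' Pipeline options
#'
#' @param analysis_rate common analysis rate in Hz (default: the encoder
#'   rate of the study design).
#' @param velocity_threshold outlier velocity bound in deg/s (default 120).
#' @param repair_window repair window in seconds (default 0.2).
#' @param discard_span a trial is discarded when a contiguous invalid span
#'   exceeds this many seconds after repair (default 1).
#' @param discard_frac ... or when more than this fraction of samples is
#'   invalid (default 0.5).
#' @param sample_k random points per trial for Bland-Altman/reliability.
#' @param seed seed driving the per-trial random sampling.
#' @param alpha one-sided level of the non-inferiority test.
#' @param ni_threshold non-inferiority margin in degrees; `NULL` uses each
#'   segment's computed global MDC95.
#' @param weighting alignment sample weighting (see [align_systems()]).
#' @param refine_encoder_zero refine encoder zeros during alignment.
#' @return a `study_options` list.
#' @export
study_options <- function(analysis_rate = NULL, velocity_threshold = 120,
                          repair_window = 0.2, discard_span = 1,
                          discard_frac = 0.5, sample_k = 10, seed = 42,
                          alpha = 0.025, ni_threshold = NULL,
                          weighting = "uniform", refine_encoder_zero = FALSE) {
  structure(list(analysis_rate = analysis_rate,
                 velocity_threshold = velocity_threshold,
                 repair_window = repair_window, discard_span = discard_span,
                 discard_frac = discard_frac, sample_k = sample_k,
                 seed = as.integer(seed), alpha = alpha,
                 ni_threshold = ni_threshold, weighting = weighting,
                 refine_encoder_zero = refine_encoder_zero),
            class = "study_options")
}

PLANES <- c("global", "flexion", "lateral_flexion", "rotation")

# One trial through zeroing, kinematics, resampling, sync, outlier repair.
# Returns aligned per-plane angle traces or a discard reason.
process_trial <- function(trial, chain, zeros, solution, options, rate) {
  man <- encoder_series_to_orientation(chain, trial$encoders, zeros)
  man <- resample_orientation(man, rate)
  ref <- resample_orientation(trial$mocap, rate)

  sync <- synchronize(man, ref)
  pair <- apply_sync(man, ref, sync)
  man <- pair$a; ref <- pair$b

  flags <- detect_outliers(ref, options$velocity_threshold) | !ref$valid
  ref <- tryCatch(repair_series(ref, flags, window = options$repair_window),
                  spineval_irreparable = function(e) NULL)
  if (is.null(ref)) {
    return(list(discarded = "irreparable reference stream: every sample flagged"))
  }
  invalid <- !(ref$valid & man$valid)
  runs <- rle(invalid)
  max_span <- if (any(runs$values)) max(runs$lengths[runs$values]) / rate else 0
  if (max_span > options$discard_span) {
    return(list(discarded = sprintf(
      "prolonged reference loss: %.2f s contiguous invalid span", max_span)))
  }
  if (mean(invalid) > options$discard_frac) {
    return(list(discarded = sprintf(
      "reference loss: %.0f%% of samples invalid", 100 * mean(invalid))))
  }

  if (!is.null(solution)) man <- apply_alignment(man, solution)
  ok <- ref$valid & man$valid
  ang_m <- anatomical_angles(man, chain$convention)[ok, ]
  ang_r <- anatomical_angles(ref, chain$convention)[ok, ]
  traces <- lapply(PLANES, function(p) cbind(man = ang_m[[p]], ref = ang_r[[p]]))
  names(traces) <- PLANES
  list(discarded = NULL, sync = sync, traces = traces, n_valid = sum(ok))
}

calibrate_segment <- function(study, segment, options, rate) {
  chain <- study$chains[[segment]]
  cal <- study$calibration[[segment]]
  if (is.null(cal)) stopf("missing calibration trial for segment '%s'", segment)

  prefix <- study$design$neutral_prefix %||% 1
  enc <- cal$encoders
  still <- enc$t <= max(0.5, prefix - 0.1)
  zeros <- zero_encoders(joint_angle_series(enc$t[still],
                                            enc$theta[still, , drop = FALSE],
                                            segment = segment,
                                            quantization = enc$quantization))

  man <- resample_orientation(encoder_series_to_orientation(chain, enc, zeros), rate)
  ref <- resample_orientation(cal$mocap, rate)
  sync <- synchronize(man, ref)
  pair <- apply_sync(man, ref, sync)
  flags <- detect_outliers(pair$b, options$velocity_threshold) | !pair$b$valid
  ref_clean <- repair_series(pair$b, flags, window = options$repair_window)
  keep <- ref_clean$valid & pair$a$valid
  man_v <- orientation_series(pair$a$t[keep], pair$a$q[keep, , drop = FALSE],
                              source = "mannequin", frame = segment)
  ref_v <- orientation_series(ref_clean$t[keep], ref_clean$q[keep, , drop = FALSE],
                              source = "reference", frame = "lab")
  sol <- align_systems(man_v, ref_v, weighting = options$weighting,
                       refine_encoder_zero = options$refine_encoder_zero,
                       chain = chain,
                       encoders = if (options$refine_encoder_zero) {
                         joint_angle_series(pair$a$t[keep],
                                            resample_encoders(enc, pair$a$t[keep]),
                                            segment = segment)
                       },
                       zero_offsets = zeros,
                       seed = options$seed)
  list(zeros = sol$encoder_zero, solution = sol, sync = sync)
}

# linear interpolation of encoder channels onto given times
resample_encoders <- function(series, t_new) {
  apply(series$theta, 2, function(x) stats::approx(series$t, x, t_new, rule = 2)$y)
}

#' Run the full validation analysis over a study
#'
#' @param study a `spine_study` from [generate_study()] or [read_study()].
#' @param options a [study_options()].
#' @return an `agreement_report`: `rmse_table`, `bland_altman`,
#'   `reliability`, `noninferiority`, `discarded`, `per_trial`, counts.
#' @export
run_study <- function(study, options = study_options()) {
  rate <- options$analysis_rate %||% study$design$encoder_rate
  segs <- study$design$segments
  calib <- lapply(segs, function(s) calibrate_segment(study, s, options, rate))
  names(calib) <- segs

  n <- length(study$trials)
  sample_seeds <- derive_seeds(options$seed, n)
  per_trial <- vector("list", n)
  discarded <- list()
  for (i in seq_len(n)) {
    tr <- study$trials[[i]]
    res <- process_trial(tr, study$chains[[tr$segment]],
                         calib[[tr$segment]]$zeros,
                         calib[[tr$segment]]$solution, options, rate)
    if (!is.null(res$discarded)) {
      discarded[[length(discarded) + 1]] <-
        data.frame(id = tr$id, segment = tr$segment, condition = tr$condition,
                   speed = tr$speed, reason = res$discarded)
      next
    }
    rmse_planes <- vapply(res$traces, function(m) rmse(m[, "man"], m[, "ref"]), 0)
    pts <- sample_points(seq_len(res$n_valid), seq_len(res$n_valid),
                         k = min(options$sample_k, res$n_valid),
                         seed = sample_seeds[i])
    sampled <- lapply(res$traces, function(m) m[pts$idx, , drop = FALSE])
    per_trial[[i]] <- list(id = tr$id, segment = tr$segment,
                           condition = tr$condition, speed = tr$speed,
                           rmse = rmse_planes, sampled = sampled,
                           lag = res$sync$lag, n_valid = res$n_valid)
  }
  analyzed <- per_trial[!vapply(per_trial, is.null, TRUE)]
  discarded <- if (length(discarded)) do.call(rbind, discarded) else
    data.frame(id = character(0), segment = character(0),
               condition = character(0), speed = character(0),
               reason = character(0))

  rmse_table <- do.call(rbind, lapply(segs, function(s) {
    rows <- analyzed[vapply(analyzed, `[[`, "", "segment") == s]
    do.call(rbind, lapply(PLANES, function(p) {
      vals <- vapply(rows, function(r) r$rmse[[p]], 0)
      data.frame(segment = s, plane = p, mean_rmse = mean(vals),
                 sd_rmse = stats::sd(vals),
                 band = as.character(interpret_rmse(mean(vals))),
                 n_trials = length(vals))
    }))
  }))

  pooled <- function(s, p) {
    rows <- analyzed[vapply(analyzed, `[[`, "", "segment") == s]
    m <- do.call(rbind, lapply(rows, function(r) r$sampled[[p]]))
    m
  }
  bland_altman_tbl <- do.call(rbind, lapply(segs, function(s) {
    do.call(rbind, lapply(setdiff(PLANES, "global"), function(p) {
      m <- pooled(s, p)
      ba <- bland_altman(m[, "man"], m[, "ref"])
      data.frame(segment = s, plane = p, bias = ba$bias, sd_diff = ba$sd_diff,
                 loa_low = ba$loa_low, loa_high = ba$loa_high,
                 shapiro_W = ba$shapiro_W, normality_ok = ba$normality_ok,
                 n = ba$n)
    }))
  }))
  reliability_tbl <- do.call(rbind, lapply(segs, function(s) {
    do.call(rbind, lapply(PLANES, function(p) {
      m <- pooled(s, p)
      rel <- reliability_sem_mdc(m[, "man"], m[, "ref"])
      data.frame(segment = s, plane = p, r = rel$r, sd = rel$sd,
                 sem = rel$sem, mdc95 = rel$mdc95, n = rel$n)
    }))
  }))
  noninferiority_tbl <- do.call(rbind, lapply(segs, function(s) {
    rows <- analyzed[vapply(analyzed, `[[`, "", "segment") == s]
    speeds <- vapply(rows, `[[`, "", "speed")
    gl <- vapply(rows, function(r) r$rmse[["global"]], 0)
    thr <- options$ni_threshold %||%
      reliability_tbl$mdc95[reliability_tbl$segment == s &
                              reliability_tbl$plane == "global"]
    ni <- noninferiority_speed(gl[speeds == "fast"], gl[speeds == "slow"],
                               threshold = thr, alpha = options$alpha)
    data.frame(segment = s, mean_diff = ni$mean_diff, threshold = ni$threshold,
               t_stat = ni$t_stat, p_value = ni$p_value,
               reject_h0 = ni$reject_h0)
  }))

  structure(list(rmse_table = rmse_table, bland_altman = bland_altman_tbl,
                 reliability = reliability_tbl,
                 noninferiority = noninferiority_tbl,
                 discarded = discarded,
                 calibration = lapply(calib, function(cc) list(
                   residual_rmse = cc$solution$residual_rmse,
                   encoder_zero = cc$zeros,
                   lag = cc$sync$lag)),
                 n_input = n, n_analyzed = length(analyzed),
                 n_discarded = nrow(discarded),
                 per_trial = analyzed),
            class = "agreement_report")
}

fmt_tbl <- function(df, digits = 1) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) round_half_up(x, digits))
  df
}

#' @export
print.agreement_report <- function(x, digits = 1, ...) {
  cat(sprintf("Agreement report: %d trials analyzed, %d discarded (of %d)\n\n",
              x$n_analyzed, x$n_discarded, x$n_input))
  cat("Root-mean-square error (deg):\n")
  print(fmt_tbl(x$rmse_table, digits), row.names = FALSE)
  cat("\nBland-Altman (deg):\n")
  print(fmt_tbl(x$bland_altman[, c("segment", "plane", "bias", "loa_low",
                                   "loa_high", "normality_ok")], digits),
        row.names = FALSE)
  cat("\nReliability / SEM / MDC95 (deg):\n")
  rel <- x$reliability
  rel$r <- round(rel$r, 3)
  rel[c("sd", "sem", "mdc95")] <- lapply(rel[c("sd", "sem", "mdc95")],
                                         round_half_up, digits)
  print(rel, row.names = FALSE)
  cat("\nNon-inferiority of fast vs slow motion (global RMSE):\n")
  print(fmt_tbl(x$noninferiority, 3), row.names = FALSE)
  if (x$n_discarded > 0) {
    cat("\nDiscarded trials:\n")
    print(x$discarded, row.names = FALSE)
  }
  invisible(x)
}
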