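#' @title Study and report file I/O
#'
#' @description
#' Trials are exchanged as plain delimited text (UTF-8, '.' decimal, header
#' row): encoder files carry `t, th1..th4` and orientation files carry
#' `t, qw, qx, qy, qz, valid`. Numbers are written at 15 significant digits,
#' which round-trips doubles exactly, so `write(read(x))` reproduces a
#' canonical file byte for byte. Reports serialise to JSON plus rendered
#' text tables.
#'
#' @name study-io
NULL

fmt_num <- function(x) sprintf("%.15g", x)

write_delim_exact <- function(df, path) {
  is_num <- vapply(df, is.numeric, TRUE)
  df[is_num] <- lapply(df[is_num], fmt_num)
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(unname(df), sep = ",")))
  writeLines(lines, path, useBytes = TRUE)
}

#' Write one trial's streams to CSV files
#'
#' Creates `<id>_encoders.csv` and `<id>_mocap.csv` under `dir`.
#'
#' @param trial a trial record (see [generate_study()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  enc <- trial$encoders
  f1 <- file.path(dir, paste0(trial$id, "_encoders.csv"))
  write_delim_exact(data.frame(t = enc$t, enc$theta, check.names = FALSE), f1)
  moc <- trial$mocap
  f2 <- file.path(dir, paste0(trial$id, "_mocap.csv"))
  write_delim_exact(data.frame(t = moc$t, moc$q,
                               valid = as.integer(moc$valid),
                               check.names = FALSE), f2)
  invisible(c(f1, f2))
}

read_csv_schema <- function(path, expected) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), expected)) {
    stopf("%s: expected columns %s, found %s", basename(path),
          paste(expected, collapse = ","), paste(names(df), collapse = ","))
  }
  df
}

#' Read one trial's streams back
#'
#' Quaternions are validated but not renormalised on read, preserving exact
#' round-trips.
#'
#' @param dir directory holding the CSV files.
#' @param id trial identifier.
#' @param segment spine segment of the trial.
#' @param meta optional list of extra metadata fields to attach.
#' @return a trial record with `encoders` and `mocap` series.
#' @export
read_trial <- function(dir, id, segment, meta = list()) {
  enc <- read_csv_schema(file.path(dir, paste0(id, "_encoders.csv")),
                         c("t", "th1", "th2", "th3", "th4"))
  moc <- read_csv_schema(file.path(dir, paste0(id, "_mocap.csv")),
                         c("t", "qw", "qx", "qy", "qz", "valid"))
  q <- as.matrix(moc[, c("qw", "qx", "qy", "qz")])
  nrm <- sqrt(rowSums(q^2))
  if (any(moc$valid == 1 & abs(nrm - 1) > 1e-6)) {
    stopf("%s_mocap.csv contains non-unit quaternions", id)
  }
  mocap <- orientation_series(moc$t, q, valid = moc$valid == 1,
                              source = "reference", frame = "lab")
  mocap$q <- q  # keep exact bytes: skip renormalisation
  c(list(id = id, segment = segment,
         encoders = joint_angle_series(enc$t, as.matrix(enc[, 2:5]),
                                       segment = segment),
         mocap = mocap),
    meta)
}

#' Write a full study to a directory
#'
#' Layout: `design.json`, `ledger.json`, `trials.json` (metadata) and a
#' `trials/` folder with two CSVs per trial (calibration trials included).
#'
#' @param study a `spine_study`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "trials"), recursive = TRUE, showWarnings = FALSE)
  all_trials <- c(study$trials, study$calibration)
  for (tr in all_trials) write_trial(tr, file.path(dir, "trials"))
  meta <- lapply(all_trials, function(tr) {
    tr[c("id", "segment", "condition", "speed", "rep", "period", "amplitude",
         "seed", "calibration")]
  })
  jsonlite::write_json(unname(meta), file.path(dir, "trials.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(study$design), file.path(dir, "design.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(study$ledger, file.path(dir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir study directory.
#' @param chains optional named list of `dh_chain`s (default: packaged
#'   models for the segments present).
#' @return a `spine_study` (without ground-truth orientation streams).
#' @export
read_study <- function(dir, chains = NULL) {
  design <- jsonlite::read_json(file.path(dir, "design.json"), simplifyVector = TRUE)
  design <- do.call(study_design, design[setdiff(names(design), character(0))])
  meta <- jsonlite::read_json(file.path(dir, "trials.json"), simplifyVector = FALSE)
  ledger <- jsonlite::read_json(file.path(dir, "ledger.json"), simplifyVector = TRUE)
  if (is.null(chains)) {
    chains <- stats::setNames(lapply(design$segments, spine_chain), design$segments)
  }
  trials <- list(); calibration <- list()
  for (m in meta) {
    tr <- read_trial(file.path(dir, "trials"), m$id, m$segment,
                     meta = m[setdiff(names(m), c("id", "segment"))])
    if (isTRUE(m$calibration)) calibration[[m$segment]] <- tr
    else trials[[m$id]] <- tr
  }
  structure(list(design = design, noise = NULL, chains = chains,
                 trials = trials, calibration = calibration, ledger = ledger),
            class = "spine_study")
}

#' Serialise an agreement report
#'
#' Writes `<path>.json` (machine-readable, deterministic) and `<path>.txt`
#' (the rendered tables).
#'
#' @param report an `agreement_report`.
#' @param path output path without extension.
#' @return invisibly, the JSON path.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  json_path <- paste0(path, ".json")
  payload <- report[c("rmse_table", "bland_altman", "reliability",
                      "noninferiority", "discarded", "calibration",
                      "n_input", "n_analyzed", "n_discarded")]
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, dataframe = "rows")
  txt <- utils::capture.output(print(report))
  writeLines(txt, paste0(path, ".txt"), useBytes = TRUE)
  invisible(json_path)
}
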