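# Portable array container: flat little-endian doubles in column-major order
# plus a one-line text sidecar carrying shape/dtype/order, so any language can
# round-trip the arrays bit-exactly.

#' Write a numeric array to a portable binary container
#'
#' @param x numeric vector, matrix or array.
#' @param path output path for the binary payload; a `<path>.meta` text
#'   sidecar (shape, dtype, order) is written next to it.
#' @return `path`, invisibly.
#' @export
write_array <- function(x, path) {
  dims <- dim(x)
  if (is.null(dims)) dims <- length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8L, endian = "little")
  writeLines(sprintf("shape=%s dtype=float64 order=column-major",
                     paste(dims, collapse = "x")),
             paste0(path, ".meta"))
  invisible(path)
}

#' Read an array written by [write_array()]
#'
#' @param path path to the binary payload (the `.meta` sidecar must exist).
#' @return numeric array with the recorded shape.
#' @export
read_array <- function(path) {
  meta <- readLines(paste0(path, ".meta"), n = 1L)
  shape_str <- sub(".*shape=([0-9x]+).*", "\\1", meta)
  dims <- as.integer(strsplit(shape_str, "x", fixed = TRUE)[[1]])
  n <- prod(dims)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = n, size = 8L, endian = "little")
  if (length(x) != n) stop(sprintf("expected %d values in %s, found %d", n, path, length(x)))
  if (length(dims) > 1L) dim(x) <- dims
  x
}

#' Write a cohort to a documented directory layout
#'
#' One subdirectory per subject with delimited-text trial/questionnaire
#' tables and array containers for the patterns and time series, plus a
#' cohort-level `manifest.tsv` echoing the configuration and seed.
#'
#' @param cohort list of `wmo_subject` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param config the `sim_config` used (echoed into the manifest).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort) {
    sd <- file.path(dir, s$subject_id)
    dir.create(sd, showWarnings = FALSE)
    trials <- s$schedule
    trials$executed_operation <- s$executed_operations
    utils::write.table(trials, file.path(sd, "trials.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    q <- cbind(s$questionnaires, latent_difficulty = s$latent_difficulty)
    utils::write.table(q, file.path(sd, "questionnaires.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_array(s$trial_patterns, file.path(sd, "patterns.bin"))
    for (i in seq_along(s$rest_timeseries)) {
      write_array(s$rest_timeseries[[i]], file.path(sd, sprintf("rest_run%d.bin", i)))
    }
    write_array(s$task_timeseries, file.path(sd, "task.bin"))
  }
  manifest <- data.frame(key = "package_version",
                         value = as.character(utils::packageVersion("wmogradients")))
  if (!is.null(config)) {
    scalars <- c("n_subjects", "n_parcels", "trials_per_operation",
                 "voxels_per_parcel", "tr_seconds", "rest_run_timepoints",
                 "n_rest_runs", "scale_noise_sd", "pattern_noise_sd",
                 "mean_signal_snr", "noise_rank", "trial_duration_tr",
                 "trial_gap_tr", "seed")
    manifest <- rbind(manifest,
                      data.frame(key = scalars,
                                 value = vapply(scalars, function(k)
                                   as.character(config[[k]]), character(1))))
    utils::write.table(data.frame(parcel = seq_along(config$network_labels),
                                  network = config$network_labels),
                       file.path(dir, "network_labels.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param path cohort directory.
#' @return list with `cohort` (list of `wmo_subject`), `network_labels`
#'   (factor, if stored), and `manifest` (data.frame).
#' @export
read_cohort <- function(path) {
  if (!dir.exists(path)) stop(sprintf("cohort directory does not exist: %s", path))
  manifest_path <- file.path(path, "manifest.tsv")
  if (!file.exists(manifest_path)) stop("manifest.tsv missing: not a cohort directory")
  manifest <- utils::read.delim(manifest_path, colClasses = "character")
  subdirs <- sort(list.dirs(path, recursive = FALSE))
  cohort <- lapply(subdirs, function(sd) {
    trials <- utils::read.delim(file.path(sd, "trials.tsv"))
    need <- c("trial", "operation", "onset_tr", "duration_tr")
    if (!all(need %in% names(trials))) {
      stop(sprintf("trials.tsv in %s is missing column(s): %s", basename(sd),
                   paste(setdiff(need, names(trials)), collapse = ", ")))
    }
    q <- utils::read.delim(file.path(sd, "questionnaires.tsv"))
    rest_files <- sort(list.files(sd, pattern = "^rest_run[0-9]+\\.bin$",
                                  full.names = TRUE))
    structure(list(
      subject_id = basename(sd),
      trial_patterns = read_array(file.path(sd, "patterns.bin")),
      trial_operations = factor(trials$operation, levels = .operations),
      executed_operations = factor(trials$executed_operation, levels = .operations),
      rest_timeseries = lapply(rest_files, read_array),
      task_timeseries = read_array(file.path(sd, "task.bin")),
      schedule = trials[, setdiff(names(trials), "executed_operation")],
      questionnaires = q[, c("WBSI", "PSWQ", "RRS_brooding"), drop = FALSE],
      latent_difficulty = q$latent_difficulty
    ), class = "wmo_subject")
  })
  labels <- NULL
  lab_path <- file.path(path, "network_labels.tsv")
  if (file.exists(lab_path)) {
    lab <- utils::read.delim(lab_path)
    if (!all(c("parcel", "network") %in% names(lab))) {
      stop("network_labels.tsv must have columns parcel, network")
    }
    P <- dim(cohort[[1]]$trial_patterns)[1]
    missing <- setdiff(seq_len(P), lab$parcel)
    if (length(missing)) {
      stop(sprintf("network label missing for parcel(s): %s",
                   paste(missing, collapse = ", ")))
    }
    labels <- factor(lab$network[order(lab$parcel)], levels = .networks)
  }
  list(cohort = cohort, network_labels = labels, manifest = manifest)
}
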