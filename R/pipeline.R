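#' Pipeline parameters
#'
#' Collects every tunable stage parameter with its study default: 30 s rest
#' windows, top-10% thresholding, 3 gradient components, alpha = 0.5,
#' stratified 4-fold decoding, covariance shrinkage 0.05, FDR 0.05.
#'
#' @param window_seconds rest RSA window length in seconds.
#' @param top_fraction row-wise threshold fraction.
#' @param n_components gradients retained.
#' @param alpha anisotropic diffusion parameter.
#' @param cv_folds decoding folds.
#' @param shrinkage Mahalanobis covariance shrinkage gamma.
#' @param fdr_alpha FDR significance threshold.
#' @param variance_floor minimum summed variance explained by the retained
#'   gradients for a solution to be marked valid.
#' @param center_mode eccentricity centering (`"grand_mean"` or `"origin"`).
#' @param include_fc,include_rest,include_decoding stage toggles.
#' @param seed seed for the decoding fold assignment.
#' @return list of class `wmo_params`.
#' @export
pipeline_params <- function(window_seconds = 30, top_fraction = 0.10,
                            n_components = 3L, alpha = 0.5, cv_folds = 4L,
                            shrinkage = 0.05, fdr_alpha = 0.05,
                            variance_floor = 0.5,
                            center_mode = "grand_mean",
                            include_fc = TRUE, include_rest = TRUE,
                            include_decoding = TRUE, seed = 1L) {
  structure(as.list(environment()), class = "wmo_params")
}

# gradient sets for one family of per-subject matrices:
# matrices[[subject]][[condition]] -> aligned wmo_gradients
#' @keywords internal
#' @noRd
.family_gradients <- function(matrices, params) {
  affs <- lapply(matrices, function(by_cond) {
    lapply(by_cond, affinity_from_matrix, top_fraction = params$top_fraction)
  })
  flat <- unlist(affs, recursive = FALSE)
  template <- build_group_template(flat, n_components = params$n_components,
                                   alpha = params$alpha)
  grads <- lapply(affs, function(by_cond) {
    lapply(by_cond, function(a) {
      g <- diffusion_map_embed(a, n_components = params$n_components,
                               alpha = params$alpha)
      g <- check_variance_floor(g, params$variance_floor)
      align_to_template(g, template)
    })
  })
  list(gradients = grads, template = template)
}

#' Analyze a cohort in memory
#'
#' Runs the full analysis chain on a generated (or ingested) cohort:
#' operation RSA and task/rest connectivity matrices, aligned diffusion-map
#' gradients per matrix family, eccentricity/dispersion tables, one-vs-other
#' decoding with its accuracy principal component, the composite
#' thought-control-difficulties score, screening regressions per metric
#' family, and the staged hierarchical models.
#'
#' @param cohort list of `wmo_subject`.
#' @param network_labels factor of parcel labels.
#' @param tr_seconds repetition time of the task/rest series.
#' @param params a [pipeline_params()].
#' @return list with `composite`, `metrics` (tidy table over all families),
#'   `accuracy` (per-subject table), `accuracy_pc`, `screening` (per-family
#'   regression tables), `stages`, `templates`, and `gradients`.
#' @export
analyze_cohort <- function(cohort, network_labels, tr_seconds = 0.46,
                           params = pipeline_params()) {
  subj_ids <- vapply(cohort, function(s) s$subject_id, character(1))

  scales <- do.call(rbind, lapply(cohort, function(s) s$questionnaires))
  scales$subject <- subj_ids
  composite <- composite_difficulty(scales)

  families <- list()
  families$rsa <- lapply(cohort, subject_rsa_matrices)
  names(families$rsa) <- subj_ids
  if (params$include_fc) {
    families$fc <- lapply(cohort, subject_task_connectivity, tr_seconds = tr_seconds)
    names(families$fc) <- subj_ids
  }
  if (params$include_rest) {
    families$rest_rsa <- lapply(cohort, function(s) {
      w <- segment_windows(s$rest_timeseries, tr_seconds, params$window_seconds)
      list(rest = rest_rsa_matrix(w)$mean_matrix)
    })
    names(families$rest_rsa) <- subj_ids
    families$rest_fc <- lapply(cohort, function(s) {
      list(rest = rest_connectivity(s$rest_timeseries))
    })
    names(families$rest_fc) <- subj_ids
  }

  metrics <- list()
  templates <- list()
  gradients <- list()
  for (fam in names(families)) {
    fg <- .family_gradients(families[[fam]], params)
    templates[[fam]] <- fg$template
    gradients[[fam]] <- fg$gradients
    metrics[[fam]] <- network_metric_table(fg$gradients, network_labels,
                                           family = fam,
                                           center_mode = params$center_mode,
                                           shrinkage = params$shrinkage)
  }
  metric_table <- do.call(rbind, metrics)
  rownames(metric_table) <- NULL

  accuracy_table <- NULL
  pc <- NULL
  if (params$include_decoding) {
    profiles <- lapply(seq_along(cohort), function(i) {
      ovr_accuracy(decoding_features(cohort[[i]]), cohort[[i]]$trial_operations,
                   cv_folds = params$cv_folds, seed = params$seed + i)
    })
    accuracy_table <- data.frame(subject = subj_ids,
                                 t(vapply(profiles, function(p) p$accuracy, numeric(4))),
                                 mean_auc = vapply(profiles, function(p) p$mean_auc, numeric(1)),
                                 included = vapply(profiles, function(p) p$included, logical(1)))
    pc <- accuracy_pc(profiles)
  }

  screening <- list()
  for (fam in names(metrics)) {
    for (vc in c("eccentricity", "dispersion")) {
      screening[[paste(fam, vc, sep = "_")]] <-
        screen_regressions(metrics[[fam]], composite, family = paste(fam, vc, sep = "_"),
                           value_col = vc, alpha = params$fdr_alpha)
    }
  }
  if (!is.null(accuracy_table)) {
    screening$accuracy <- screen_accuracy_regressions(accuracy_table, composite,
                                                      alpha = params$fdr_alpha)
  }

  stages <- NULL
  if (!is.null(pc)) {
    stages <- .auto_stages(pc, metrics, screening, composite, params)
  }

  list(composite = composite, metrics = metric_table, accuracy = accuracy_table,
       accuracy_pc = pc, screening = screening, stages = stages,
       templates = templates, gradients = gradients)
}

#' Accuracy screening regressions
#'
#' Simple regressions of the composite score on each operation's decoding
#' accuracy, FDR-adjusted within the family of four.
#'
#' @param accuracy_table data.frame with `subject` and one column per
#'   operation.
#' @param composite data.frame with `subject` and `composite`.
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame, one row per operation.
#' @export
screen_accuracy_regressions <- function(accuracy_table, composite, alpha = 0.05) {
  dat <- merge(accuracy_table, composite[, c("subject", "composite")], by = "subject")
  rows <- lapply(.operations, function(op) {
    fit <- stats::lm(dat$composite ~ dat[[op]])
    sm <- summary(fit)
    data.frame(family = "accuracy", operation = op,
               estimate = stats::coef(fit)[[2L]],
               t = stats::coef(sm)[2L, "t value"],
               F = unname(sm$fstatistic[1L]),
               adjusted_r2 = sm$adj.r.squared,
               p = stats::coef(sm)[2L, "Pr(>|t|)"])
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_fdr < alpha
  out
}

# carry significant RSA metrics (and the strongest significant connectivity
# metric, if any) into the staged models
#' @keywords internal
#' @noRd
.auto_stages <- function(pc, metrics, screening, composite, params) {
  pull_metric <- function(fam, vc, cond, nw) {
    tab <- metrics[[fam]]
    sub <- tab[tab$condition == cond & tab$network == nw, ]
    sub <- sub[order(sub$subject), ]
    sub[[vc]]
  }
  rsa_cols <- list()
  for (vc in c("eccentricity", "dispersion")) {
    scr <- screening[[paste0("rsa_", vc)]]
    sig <- scr[scr$significant, , drop = FALSE]
    for (i in seq_len(nrow(sig))) {
      nm <- sprintf("rsa_%s_%s_%s", vc, sig$condition[i], sig$network[i])
      rsa_cols[[nm]] <- pull_metric("rsa", vc, sig$condition[i], sig$network[i])
    }
  }
  fc_metric <- NULL
  if (!is.null(screening$fc_eccentricity)) {
    fc_sig <- rbind(
      cbind(screening$fc_eccentricity, metric = "eccentricity"),
      cbind(screening$fc_dispersion, metric = "dispersion")
    )
    fc_sig <- fc_sig[fc_sig$significant, , drop = FALSE]
    if (nrow(fc_sig)) {
      best <- fc_sig[which.min(fc_sig$p_fdr), ]
      fc_metric <- pull_metric("fc", best$metric, best$condition, best$network)
    }
  }
  comp <- composite[order(composite$subject), ]
  if (!length(rsa_cols)) {
    return(list(stage1 = hierarchical_stages(pc$scores, NULL, NULL, comp)$stage1,
                stage2 = list(), stage3 = list()))
  }
  hierarchical_stages(pc$scores, as.data.frame(rsa_cols), fc_metric, comp)
}

#' Run the full pipeline end to end
#'
#' Generates (or re-reads) a cohort, runs [analyze_cohort()], and writes the
#' tidy outputs plus a manifest with the package version, configuration echo,
#' seed, and per-file checksums to a run directory.
#'
#' @param config a [sim_config()].
#' @param out_dir run directory to create.
#' @param params a [pipeline_params()].
#' @param simulate if `FALSE`, re-read a cohort previously written under
#'   `out_dir/cohort` instead of generating a new one.
#' @param write_cohort_files if `TRUE` (default) write the generated cohort
#'   to `out_dir/cohort`.
#' @return the [analyze_cohort()] result, invisibly, with `out_dir` attached.
#' @export
run_pipeline <- function(config, out_dir, params = pipeline_params(),
                         simulate = TRUE, write_cohort_files = TRUE) {
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort_dir <- file.path(out_dir, "cohort")
  if (simulate) {
    cohort <- generate_cohort(config)
    labels <- config$network_labels
    if (write_cohort_files) write_cohort(cohort, cohort_dir, config)
  } else {
    if (!dir.exists(cohort_dir)) {
      stop(sprintf("simulate = FALSE but no cohort directory at %s", cohort_dir))
    }
    cc <- read_cohort(cohort_dir)
    cohort <- cc$cohort
    labels <- if (is.null(cc$network_labels)) config$network_labels else cc$network_labels
  }
  res <- analyze_cohort(cohort, labels, tr_seconds = config$tr_seconds, params = params)

  utils::write.table(res$metrics, file.path(out_dir, "network_metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(res$composite, file.path(out_dir, "composite.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(res$accuracy)) {
    utils::write.table(res$accuracy, file.path(out_dir, "accuracy.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  screening_all <- do.call(rbind, lapply(names(res$screening), function(nm) {
    s <- res$screening[[nm]]
    if (!"network" %in% names(s)) {
      s$network <- NA_character_
      s$condition <- s$operation
      s$operation <- NULL
    }
    s[, c("family", "condition", "network", "estimate", "t", "F",
          "adjusted_r2", "p", "p_fdr", "significant")]
  }))
  utils::write.table(screening_all, file.path(out_dir, "screening.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(res$stages)) {
    utils::write.table(model_report_table(res$stages),
                       file.path(out_dir, "stage_models.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out_files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- data.frame(
    key = c("package_version", "seed", "n_subjects", "n_parcels", "elapsed_s",
            basename(out_files)),
    value = c(as.character(utils::packageVersion("wmogradients")),
              config$seed, config$n_subjects, config$n_parcels,
              sprintf("%.1f", as.numeric(difftime(Sys.time(), t0, units = "secs"))),
              unname(tools::md5sum(out_files)))
  )
  utils::write.table(manifest, file.path(out_dir, "run_manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  res$out_dir <- out_dir
  invisible(res)
}
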