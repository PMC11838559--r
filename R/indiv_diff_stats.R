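#' Composite thought-control-difficulties score
#'
#' Z-scores each questionnaire total over the cohort (sample, n-1, standard
#' deviation) and averages the three z-scores per subject.
#'
#' @param scale_table data.frame with columns `WBSI`, `PSWQ`, `RRS_brooding`
#'   (one row per subject) and optionally `subject`.
#' @return data.frame with the three z columns and `composite`.
#' @export
composite_difficulty <- function(scale_table) {
  need <- c("WBSI", "PSWQ", "RRS_brooding")
  if (!all(need %in% names(scale_table))) {
    stop(sprintf("missing scale column(s): %s",
                 paste(setdiff(need, names(scale_table)), collapse = ", ")))
  }
  z <- lapply(need, function(nm) {
    v <- scale_table[[nm]]
    s <- stats::sd(v)
    if (!is.finite(s) || s < .Machine$double.eps) {
      stop(sprintf("scale %s has zero variance across the cohort", nm))
    }
    (v - mean(v)) / s
  })
  out <- data.frame(z_wbsi = z[[1]], z_pswq = z[[2]], z_brooding = z[[3]])
  out$composite <- rowMeans(as.matrix(out))
  if (!is.null(scale_table$subject)) out <- cbind(subject = scale_table$subject, out)
  out
}

#' @keywords internal
#' @noRd
.model_report <- function(fit, model_id, vs_fit = NULL, vs_id = NA_character_) {
  sm <- summary(fit)
  coefs <- stats::coef(sm)
  fstat <- sm$fstatistic
  nested <- NULL
  if (!is.null(vs_fit)) {
    an <- stats::anova(vs_fit, fit)
    nested <- list(vs_model = vs_id,
                   F_change = an$F[2L],
                   p_change = an$`Pr(>F)`[2L])
  }
  vif <- NULL
  preds <- attr(stats::terms(fit), "term.labels")
  if (length(preds) >= 2L) vif <- car::vif(fit)
  structure(list(
    model_id = model_id,
    predictors = preds,
    F = if (is.null(fstat)) NA_real_ else unname(fstat[1L]),
    df = if (is.null(fstat)) c(NA, NA) else unname(fstat[2:3]),
    r2 = sm$r.squared,
    adjusted_r2 = sm$adj.r.squared,
    coefficients = data.frame(term = rownames(coefs),
                              estimate = coefs[, 1L], t = coefs[, 3L],
                              p = coefs[, 4L], row.names = NULL),
    nested_comparison = nested,
    vif = vif,
    fit = fit
  ), class = "wmo_model_report")
}

#' @export
print.wmo_model_report <- function(x, ...) {
  cat(sprintf("<model %s: %s>\n  F = %.3f, adj R2 = %.3f\n", x$model_id,
              paste(x$predictors, collapse = " + "), x$F, x$adjusted_r2))
  if (!is.null(x$nested_comparison)) {
    cat(sprintf("  vs %s: F_change = %.3f, p = %.4f\n",
                x$nested_comparison$vs_model, x$nested_comparison$F_change,
                x$nested_comparison$p_change))
  }
  if (!is.null(x$vif)) {
    cat(sprintf("  VIF: %s\n", paste(sprintf("%s=%.2f", names(x$vif), x$vif),
                                     collapse = ", ")))
  }
  invisible(x)
}

#' Screening regressions of one metric family
#'
#' One ordinary-least-squares simple regression of the composite score on
#' each (condition, network) metric in the family, with Benjamini-Hochberg
#' FDR adjustment across the family (16 models for a full 4 x 4 family) and a
#' flag at `p_fdr < alpha`.
#'
#' @param metric_table data.frame with columns `subject`, `condition`,
#'   `network`, and the metric column named by `value_col`.
#' @param composite data.frame with columns `subject` and `composite`.
#' @param family label for the family (e.g. `"rsa_eccentricity"`).
#' @param value_col metric column name (default `"eccentricity"`).
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame, one row per model: condition, network, estimate, t, F,
#'   adjusted_r2, p, p_fdr, significant.
#' @export
screen_regressions <- function(metric_table, composite, family = "metric",
                               value_col = "eccentricity", alpha = 0.05) {
  n_subj <- length(unique(composite$subject))
  if (n_subj < 10L) stop("need at least 10 subjects for screening regressions")
  cells <- unique(metric_table[, c("condition", "network")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cond <- cells$condition[i]; nw <- cells$network[i]
    sub <- metric_table[metric_table$condition == cond & metric_table$network == nw, ]
    dat <- merge(sub[, c("subject", value_col)], composite[, c("subject", "composite")],
                 by = "subject")
    dat$value <- dat[[value_col]]
    fit <- stats::lm(composite ~ value, data = dat)
    sm <- summary(fit)
    data.frame(family = family, condition = cond, network = nw,
               estimate = stats::coef(fit)[["value"]],
               t = stats::coef(sm)["value", "t value"],
               F = unname(sm$fstatistic[1L]),
               adjusted_r2 = sm$adj.r.squared,
               p = stats::coef(sm)["value", "Pr(>|t|)"])
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_fdr < alpha
  out
}

#' Staged hierarchical regressions
#'
#' Stage 1 regresses the composite score on the accuracy principal component
#' alone. Stage 2 adds, one at a time, each carried-forward RSA gradient
#' metric and compares each nested model to Stage 1 with the F-test for
#' nested models. Stage 3 adds the connectivity gradient metric to each
#' Stage-2 model, again with nested comparisons. VIF is reported whenever two
#' or more predictors co-enter.
#'
#' @param accuracy_pc numeric vector of PC scores, one per subject (aligned
#'   with `composite`).
#' @param rsa_metrics data.frame (subjects x metrics) of carried-forward RSA
#'   metrics; may have zero columns.
#' @param connectivity_metric numeric vector, or `NULL` to skip Stage 3.
#' @param composite data.frame with column `composite` (one row per subject,
#'   same order).
#' @return list with elements `stage1` (a `wmo_model_report`), `stage2` and
#'   `stage3` (lists of reports, one per RSA metric).
#' @export
hierarchical_stages <- function(accuracy_pc, rsa_metrics, connectivity_metric,
                                composite) {
  dat <- data.frame(composite = composite$composite, pc = accuracy_pc)
  if (!is.null(rsa_metrics) && ncol(as.data.frame(rsa_metrics)) > 0L) {
    rsa_metrics <- as.data.frame(rsa_metrics)
    if (nrow(rsa_metrics) != nrow(dat)) stop("rsa_metrics rows must match subjects")
    dat <- cbind(dat, rsa_metrics)
  } else {
    rsa_metrics <- NULL
  }
  if (!is.null(connectivity_metric)) dat$fc_metric <- connectivity_metric
  if (any(!stats::complete.cases(dat))) stop("inputs are not aligned by subject (NAs)")

  qrx <- qr(as.matrix(dat[, -1L, drop = FALSE]))
  if (qrx$rank < ncol(dat) - 1L) {
    stop(sprintf("rank-deficient design; collinear column(s) among: %s",
                 paste(colnames(dat)[-1L], collapse = ", ")))
  }

  stage1 <- .model_report(stats::lm(composite ~ pc, data = dat), "stage1-pc")
  stage2 <- list()
  stage3 <- list()
  for (nm in colnames(rsa_metrics)) {
    f2 <- stats::as.formula(sprintf("composite ~ pc + `%s`", nm))
    fit2 <- stats::lm(f2, data = dat)
    id2 <- sprintf("stage2-pc+%s", nm)
    stage2[[nm]] <- .model_report(fit2, id2, vs_fit = stage1$fit, vs_id = "stage1-pc")
    if (!is.null(connectivity_metric)) {
      f3 <- stats::as.formula(sprintf("composite ~ pc + `%s` + fc_metric", nm))
      fit3 <- stats::lm(f3, data = dat)
      stage3[[nm]] <- .model_report(fit3, sprintf("stage3-pc+%s+fc", nm),
                                    vs_fit = fit2, vs_id = id2)
    }
  }
  list(stage1 = stage1, stage2 = stage2, stage3 = stage3)
}

#' Exploratory full model
#'
#' One OLS model with the accuracy PC and every significant network-metric
#' predictor entered together, with VIF per predictor and an optional nested
#' comparison against a reference model.
#'
#' @param all_significant_metrics data.frame (subjects x metrics).
#' @param accuracy_pc numeric vector of PC scores.
#' @param composite data.frame with column `composite`.
#' @param vs optional `wmo_model_report` to compare against (must be nested).
#' @return `wmo_model_report`.
#' @export
exploratory_full_model <- function(all_significant_metrics, accuracy_pc,
                                   composite, vs = NULL) {
  m <- as.data.frame(all_significant_metrics)
  n <- length(accuracy_pc)
  if (ncol(m) + 2L >= n) stop("more predictors than subjects allows")
  dat <- cbind(data.frame(composite = composite$composite, pc = accuracy_pc), m)
  preds <- c("pc", sprintf("`%s`", colnames(m)))
  fit <- stats::lm(stats::as.formula(paste("composite ~", paste(preds, collapse = " + "))),
                   data = dat)
  .model_report(fit, "exploratory-full",
                vs_fit = if (is.null(vs)) NULL else vs$fit,
                vs_id = if (is.null(vs)) NA_character_ else vs$model_id)
}

#' Flatten model reports into a tidy table
#'
#' @param reports a `wmo_model_report` or (nested) list of them.
#' @return data.frame, one row per model, echoing F, adjusted R-squared,
#'   per-predictor t and p, and nested-comparison statistics.
#' @export
model_report_table <- function(reports) {
  if (inherits(reports, "wmo_model_report")) reports <- list(reports)
  flat <- list()
  walk <- function(x) {
    if (inherits(x, "wmo_model_report")) flat[[length(flat) + 1L]] <<- x
    else if (is.list(x)) lapply(x, walk)
    invisible(NULL)
  }
  walk(reports)
  do.call(rbind, lapply(flat, function(r) {
    cf <- r$coefficients[r$coefficients$term != "(Intercept)", , drop = FALSE]
    data.frame(model_id = r$model_id,
               predictors = paste(r$predictors, collapse = "+"),
               F = r$F, adjusted_r2 = r$adjusted_r2,
               term = cf$term, t = cf$t, p = cf$p,
               F_change = if (is.null(r$nested_comparison)) NA_real_ else r$nested_comparison$F_change,
               p_change = if (is.null(r$nested_comparison)) NA_real_ else r$nested_comparison$p_change,
               row.names = NULL)
  }))
}
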