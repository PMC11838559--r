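#' One-vs-other cross-validated decoding accuracy
#'
#' For each operation, fits an L2-regularized logistic regression of that
#' operation's trials against the other three under stratified k-fold
#' cross-validation, and reports the proportion of held-out trials correctly
#' labeled by the binary decision at probability 0.5 together with the area
#' under the ROC curve. Regularization strength is fixed at 1.0 on the
#' summed-log-likelihood scale (glmnet `lambda = 1/n_train`). A subject is
#' marked excluded (`included = FALSE`) when the mean AUC falls below chance
#' (0.5).
#'
#' @param trial_features trial x feature matrix (e.g. parcel-mean patterns).
#' @param trial_operations factor of operation labels.
#' @param cv_folds number of stratified folds (default 4).
#' @param seed integer seed for the fold assignment.
#' @param lambda_strength L2 penalty on the summed-log-likelihood scale
#'   (default 1).
#' @return object of class `wmo_accuracy`: list with `accuracy` and `auc`
#'   (named per operation), `mean_auc`, and `included`.
#' @export
ovr_accuracy <- function(trial_features, trial_operations, cv_folds = 4L,
                         seed = 1L, lambda_strength = 1) {
  x <- as.matrix(trial_features)
  ops <- factor(trial_operations)
  n <- nrow(x)
  if (n != length(ops)) stop("one label per trial required")
  if (any(table(ops) < cv_folds)) stop("need at least cv_folds trials per operation")

  # stratified fold assignment: shuffle within class, deal round-robin
  folds <- integer(n)
  rng <- .with_seed(seed, {
    for (op in levels(ops)) {
      idx <- sample(which(ops == op))
      folds[idx] <- rep_len(seq_len(cv_folds), length(idx))
    }
    folds
  })
  folds <- rng

  levels_op <- levels(ops)
  acc <- auc <- stats::setNames(numeric(length(levels_op)), levels_op)
  for (op in levels_op) {
    y <- as.integer(ops == op)
    prob <- numeric(n)
    for (f in seq_len(cv_folds)) {
      test <- folds == f
      if (length(unique(y[!test])) < 2L || length(unique(y[test])) < 2L) {
        stop("a fold contains a single class; stratification failed")
      }
      fit <- glmnet::glmnet(x[!test, , drop = FALSE], y[!test],
                            family = "binomial", alpha = 0,
                            lambda = lambda_strength / sum(!test),
                            standardize = TRUE)
      prob[test] <- as.numeric(stats::predict(fit, x[test, , drop = FALSE],
                                              type = "response"))
    }
    acc[op] <- mean((prob >= 0.5) == (y == 1L))
    auc[op] <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = prob,
                                              quiet = TRUE, direction = "<",
                                              levels = c(0L, 1L))))
  }
  structure(list(accuracy = acc, auc = auc, mean_auc = mean(auc),
                 included = mean(auc) >= 0.5),
            class = "wmo_accuracy")
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
#' @keywords internal
#' @noRd
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' @export
print.wmo_accuracy <- function(x, ...) {
  cat(sprintf("<wmo_accuracy: mean acc %.3f, mean AUC %.3f%s>\n",
              mean(x$accuracy), x$mean_auc,
              if (!x$included) ", EXCLUDED (AUC < 0.5)" else ""))
  invisible(x)
}

#' Principal component of the four operation accuracies
#'
#' First principal component of the standardized per-operation accuracy
#' scores across subjects, signed so that a higher score means higher mean
#' accuracy. Constant accuracy columns are dropped with a warning before
#' standardization.
#'
#' @param profiles data.frame or matrix, subjects x operations, of accuracy
#'   scores (e.g. rows of `vapply(profiles, \(p) p$accuracy, ...)`); or a
#'   list of `wmo_accuracy` objects.
#' @return list with `scores` (per subject), `loadings`,
#'   `variance_explained` (fraction for the first component), and
#'   `n_subjects`.
#' @export
accuracy_pc <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles) &&
      inherits(profiles[[1]], "wmo_accuracy")) {
    profiles <- t(vapply(profiles, function(p) p$accuracy,
                         numeric(length(profiles[[1]]$accuracy))))
  }
  m <- as.matrix(profiles)
  if (nrow(m) < 5L * 1L || nrow(m) < 5L) {
    stop("need at least 5 subjects (five times the number of components extracted)")
  }
  sds <- apply(m, 2L, stats::sd)
  keep <- sds > .Machine$double.eps
  if (!all(keep)) {
    warning(sprintf("dropping constant accuracy column(s): %s",
                    paste(colnames(m)[!keep], collapse = ", ")))
    m <- m[, keep, drop = FALSE]
  }
  if (ncol(m) < 1L) stop("no non-constant accuracy columns left")
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1L]
  if (stats::cor(scores, rowMeans(m)) < 0) {
    scores <- -scores
    pc$rotation[, 1L] <- -pc$rotation[, 1L]
  }
  list(scores = as.numeric(scores),
       loadings = pc$rotation[, 1L],
       variance_explained = pc$sdev[1L]^2 / sum(pc$sdev^2),
       n_subjects = nrow(m))
}

#' Parcel-mean decoding features for a subject
#'
#' The desk-scale whole-brain feature vector: per trial, the mean pattern
#' value within each parcel, concatenated across parcels.
#'
#' @param subject a `wmo_subject`.
#' @return trial x parcel matrix.
#' @export
decoding_features <- function(subject) {
  t(rowMeans(subject$trial_patterns, dims = 2L))
}
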