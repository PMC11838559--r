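#' Operation contrast weights (target vs others t statistics)
#'
#' For each operation and voxel, computes the two-sample pooled-variance t
#' statistic comparing that operation's trials against all other trials, with
#' no thresholding. Voxels with zero pooled variance get weight 0.
#'
#' @param trial_patterns trial x voxel matrix for one parcel.
#' @param trial_operations factor of operation labels, one per trial.
#' @return matrix voxel x operation of t weights, with an attribute
#'   `n_zero_variance` counting zeroed voxels.
#' @export
compute_contrast_weights <- function(trial_patterns, trial_operations) {
  x <- as.matrix(trial_patterns)
  ops <- factor(trial_operations)
  if (nrow(x) != length(ops)) stop("one label per trial required")
  if (any(table(ops) < 2L)) stop("need at least 2 trials per operation")
  out <- matrix(0, ncol(x), nlevels(ops), dimnames = list(colnames(x), levels(ops)))
  n_zero <- 0L
  for (op in levels(ops)) {
    a <- ops == op
    n1 <- sum(a); n2 <- sum(!a)
    m1 <- colMeans(x[a, , drop = FALSE]); m2 <- colMeans(x[!a, , drop = FALSE])
    ss1 <- colSums(sweep(x[a, , drop = FALSE], 2L, m1, "-")^2)
    ss2 <- colSums(sweep(x[!a, , drop = FALSE], 2L, m2, "-")^2)
    sp2 <- (ss1 + ss2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    t_stat <- (m1 - m2) / se
    zero <- se < .Machine$double.eps
    if (any(zero)) {
      t_stat[zero] <- 0
      n_zero <- n_zero + sum(zero)
    }
    out[, op] <- t_stat
  }
  if (n_zero > 0L) message(sprintf("compute_contrast_weights: %d zero-variance voxel weights set to 0", n_zero))
  attr(out, "n_zero_variance") <- n_zero
  out
}

#' @keywords internal
#' @noRd
.similarity_matrix <- function(values, row_ids, kind, condition, flagged = integer()) {
  dimnames(values) <- list(row_ids, row_ids)
  structure(list(values = values, row_ids = row_ids, kind = kind,
                 condition = condition, flagged = flagged),
            class = "wmo_similarity")
}

#' @export
print.wmo_similarity <- function(x, ...) {
  cat(sprintf("<wmo_similarity %s/%s: %d x %d>\n", x$kind, x$condition,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Trial-by-trial similarity of weighted patterns
#'
#' Applies a voxel weight vector to every trial pattern and returns the
#' Pearson correlation matrix between the weighted trial vectors. Zero
#' variance trial vectors (constant after weighting) get their row/column set
#' to 0 and are flagged.
#'
#' @param trial_patterns trial x voxel matrix for one parcel.
#' @param weights voxel weight vector (e.g. one column of
#'   [compute_contrast_weights()]); `NULL` means unit weights.
#' @param condition label stored with the matrix (e.g. the weighting
#'   operation).
#' @return `wmo_similarity` of kind `"trial"`.
#' @export
trial_similarity <- function(trial_patterns, weights = NULL, condition = "all") {
  x <- as.matrix(trial_patterns)
  if (ncol(x) < 2L) stop("need at least 2 voxels per parcel")
  if (!is.null(weights)) {
    if (length(weights) != ncol(x)) stop("one weight per voxel required")
    x <- sweep(x, 2L, weights, "*")
  }
  r <- .fast_cor(t(x))                # correlate trial vectors
  flagged <- which(is.na(diag(r)))
  if (length(flagged)) {
    r[flagged, ] <- 0
    r[, flagged] <- 0
  }
  r[is.na(r)] <- 0
  diag(r) <- 1
  diag(r)[flagged] <- 0
  ids <- rownames(trial_patterns)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  .similarity_matrix(r, ids, "trial", condition, flagged)
}

#' Regional (parcel-by-parcel) RSA matrix for one operation
#'
#' Restricts each parcel's trial-similarity matrix to the given operation's
#' trials, vectorizes the strictly lower triangle, and Pearson-correlates the
#' triangle vectors across parcels: a second-order similarity of
#' representational structure. Parcels whose triangle is constant are flagged
#' and zeroed.
#'
#' @param trial_similarities list of per-parcel `wmo_similarity` (kind trial)
#'   or plain trial x trial matrices, all over the same trials.
#' @param trial_operations factor of labels for those trials.
#' @param operation one of maintain/replace/suppress/clear.
#' @return `wmo_similarity` of kind `"regional"`.
#' @export
regional_rsa_matrix <- function(trial_similarities, trial_operations, operation) {
  operation <- match.arg(operation, .operations)
  ops <- factor(trial_operations)
  keep <- which(ops == operation)
  if (length(keep) < 3L) stop("need at least 3 trials of the operation")
  tri <- vapply(trial_similarities, function(s) {
    m <- if (inherits(s, "wmo_similarity")) s$values else as.matrix(s)
    if (nrow(m) != length(ops)) stop("trial-similarity size does not match labels")
    .lower_tri(m[keep, keep, drop = FALSE])
  }, numeric(length(keep) * (length(keep) - 1L) / 2L))
  r <- .fast_cor(tri)
  flagged <- which(is.na(diag(r)))
  if (length(flagged)) {
    r[flagged, ] <- 0
    r[, flagged] <- 0
  }
  r[is.na(r)] <- 0
  diag(r) <- 1
  diag(r)[flagged] <- 0
  .similarity_matrix(r, as.character(seq_len(ncol(tri))), "regional", operation, flagged)
}

#' Segment resting runs into non-overlapping windows
#'
#' Runs are concatenated in order; each parcel is z-scored over the
#' concatenated series; the series is cut into non-overlapping windows of
#' `floor(window_seconds / tr_seconds)` time points and a trailing partial
#' window is discarded.
#'
#' @param rest_timeseries list of time x parcel matrices (or one matrix).
#' @param tr_seconds repetition time in seconds.
#' @param window_seconds window length in seconds (default 30).
#' @return list of time x parcel window matrices.
#' @export
segment_windows <- function(rest_timeseries, tr_seconds, window_seconds = 30) {
  if (window_seconds <= tr_seconds) stop("window_seconds must exceed tr_seconds")
  if (is.matrix(rest_timeseries)) rest_timeseries <- list(rest_timeseries)
  y <- do.call(rbind, rest_timeseries)
  y <- scale(y)
  attr(y, "scaled:center") <- NULL
  attr(y, "scaled:scale") <- NULL
  wlen <- floor(window_seconds / tr_seconds)
  n_win <- floor(nrow(y) / wlen)
  if (n_win < 1L) {
    stop(sprintf("series of %d time points is shorter than one %d-point window",
                 nrow(y), wlen))
  }
  lapply(seq_len(n_win), function(w) y[(w - 1L) * wlen + seq_len(wlen), , drop = FALSE])
}

#' Windowed resting-state RSA
#'
#' Computes a parcel x parcel Pearson correlation matrix within each window,
#' then (i) the window-to-window similarity matrix — Pearson correlation
#' between the lower triangles of the per-window matrices — and (ii) the
#' element-wise mean of the per-window parcel matrices, which is the 360 x 360
#' input handed to the gradient stage. Constant parcels within a window are
#' zeroed and flagged.
#'
#' @param windows list of time x parcel matrices from [segment_windows()].
#' @return list with `window_similarity` (`wmo_similarity`, kind `"window"`),
#'   `mean_matrix` (`wmo_similarity`, kind `"regional"`, condition `"rest"`),
#'   and `per_window` (list of parcel correlation matrices).
#' @export
rest_rsa_matrix <- function(windows) {
  if (length(windows) < 2L) stop("need at least 2 windows")
  per_window <- lapply(windows, function(w) {
    r <- .fast_cor(w)
    bad <- which(is.na(diag(r)))
    if (length(bad)) {
      r[bad, ] <- 0; r[, bad] <- 0
    }
    r[is.na(r)] <- 0
    diag(r) <- 1
    diag(r)[bad] <- 0
    attr(r, "flagged") <- bad
    r
  })
  tris <- vapply(per_window, .lower_tri, numeric(length(.lower_tri(per_window[[1]]))))
  wsim <- .fast_cor(tris)
  wsim[is.na(wsim)] <- 0
  diag(wsim) <- 1
  mean_mat <- Reduce(`+`, per_window) / length(per_window)
  list(
    window_similarity = .similarity_matrix(wsim, as.character(seq_along(windows)),
                                           "window", "rest"),
    mean_matrix = .similarity_matrix(mean_mat, as.character(seq_len(ncol(mean_mat))),
                                     "regional", "rest"),
    per_window = per_window
  )
}

#' Per-operation regional RSA matrices for one subject
#'
#' Convenience wrapper chaining [compute_contrast_weights()],
#' [trial_similarity()] and [regional_rsa_matrix()] over all parcels:
#' for each operation, every parcel's patterns are weighted by that
#' operation's contrast weights, the operation's trials are correlated, and
#' triangle vectors are correlated across parcels.
#'
#' @param subject a `wmo_subject` (or list with `trial_patterns` and
#'   `trial_operations`).
#' @param operations operations to compute (default all four).
#' @return named list of `wmo_similarity` regional matrices.
#' @export
subject_rsa_matrices <- function(subject, operations = .operations) {
  pat <- subject$trial_patterns
  ops <- subject$trial_operations
  P <- dim(pat)[1]
  keep_by_op <- lapply(operations, function(op) which(ops == op))
  names(keep_by_op) <- operations
  tri <- lapply(operations, function(op) {
    nk <- length(keep_by_op[[op]])
    matrix(NA_real_, nk * (nk - 1L) / 2L, P)
  })
  names(tri) <- operations
  for (p in seq_len(P)) {
    xp <- pat[p, , ]
    w <- suppressMessages(compute_contrast_weights(xp, ops))
    for (op in operations) {
      keep <- keep_by_op[[op]]
      s <- trial_similarity(xp[keep, , drop = FALSE], w[, op], condition = op)
      tri[[op]][, p] <- .lower_tri(s$values)
    }
  }
  out <- list()
  for (op in operations) {
    r <- .fast_cor(tri[[op]])
    flagged <- which(is.na(diag(r)))
    if (length(flagged)) {
      r[flagged, ] <- 0; r[, flagged] <- 0
    }
    r[is.na(r)] <- 0
    diag(r) <- 1
    diag(r)[flagged] <- 0
    out[[op]] <- .similarity_matrix(r, as.character(seq_len(P)), "regional", op, flagged)
  }
  out
}
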