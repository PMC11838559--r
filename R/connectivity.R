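#' Canonical double-gamma hemodynamic response
#'
#' The conventional two-gamma impulse response (response peak 6 s, undershoot
#' peak 16 s, undershoot ratio 6), sampled at the acquisition TR.
#'
#' @param tr_seconds sampling interval.
#' @param duration_seconds kernel length (default 32 s).
#' @param peak,undershoot gamma shape parameters in seconds.
#' @param ratio response/undershoot amplitude ratio.
#' @return numeric vector of kernel samples, scaled to peak 1.
#' @export
canonical_hrf <- function(tr_seconds, duration_seconds = 32,
                          peak = 6, undershoot = 16, ratio = 6) {
  t <- seq(0, duration_seconds, by = tr_seconds)
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  h / max(h)
}

#' Operation weight series from a trial schedule
#'
#' Builds a unit boxcar over each operation's trial epochs, convolves it with
#' the canonical double-gamma response, and rectifies negative values to zero.
#' The result is one nonnegative weight per time point per operation, used to
#' isolate operation periods in weighted connectivity.
#'
#' @param trial_schedule data.frame with columns `operation`, `onset_tr`,
#'   `duration_tr` (TR units, 0-based onsets).
#' @param tr_seconds repetition time.
#' @param n_timepoints length of the task series.
#' @param hrf kernel; defaults to [canonical_hrf()] at `tr_seconds`.
#' @return matrix time x operation of rectified weights.
#' @export
build_operation_weights <- function(trial_schedule, tr_seconds, n_timepoints,
                                    hrf = canonical_hrf(tr_seconds)) {
  if (is.null(trial_schedule) || nrow(trial_schedule) == 0L) {
    stop("trial schedule is empty")
  }
  ops <- levels(factor(trial_schedule$operation))
  out <- matrix(0, n_timepoints, length(ops), dimnames = list(NULL, ops))
  for (op in ops) {
    box <- numeric(n_timepoints)
    rows <- trial_schedule[trial_schedule$operation == op, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      idx <- rows$onset_tr[i] + seq_len(rows$duration_tr[i])
      idx <- idx[idx >= 1L & idx <= n_timepoints]
      box[idx] <- 1
    }
    w <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n_timepoints)]
    out[, op] <- pmax(w, 0)
  }
  if (any(colSums(out) <= 0)) stop("an operation has no positive weight")
  out
}

#' @keywords internal
#' @noRd
.fisher_z <- function(r, bound = 1 - 1e-7) atanh(.clip(r, -bound, bound))

#' @keywords internal
#' @noRd
.connectivity_object <- function(z, condition, flagged = integer()) {
  diag(z) <- 0
  structure(list(values = z, condition = condition, flagged = flagged),
            class = "wmo_connectivity")
}

#' @export
print.wmo_connectivity <- function(x, ...) {
  cat(sprintf("<wmo_connectivity %s: %d x %d Fisher-z>\n", x$condition,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Weighted task functional connectivity
#'
#' Weighted Pearson correlation between every pair of parcels (weighted
#' means, variances and covariances via [stats::cov.wt()]), followed by the
#' Fisher transform with correlations clipped to `±(1 - 1e-7)`. Pairs
#' involving a parcel with zero weighted variance are set to 0 and flagged.
#' Optional nuisance regressors are residualized out of the series first.
#'
#' @param timeseries time x parcel matrix.
#' @param weights nonnegative weight per time point (one operation's column
#'   of [build_operation_weights()]).
#' @param condition label stored with the matrix.
#' @param nuisance optional time x k matrix of regressors to remove.
#' @return `wmo_connectivity` with Fisher-z values, diagonal 0.
#' @export
weighted_connectivity <- function(timeseries, weights, condition = "task",
                                  nuisance = NULL) {
  y <- as.matrix(timeseries)
  if (length(weights) != nrow(y)) stop("one weight per time point required")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) <= 0) stop("total weight is zero")
  if (!is.null(nuisance)) {
    y <- stats::lm.fit(cbind(1, as.matrix(nuisance)), y)$residuals
  }
  cw <- stats::cov.wt(y, wt = weights / sum(weights), cor = TRUE)
  r <- cw$cor
  bad <- which(!is.finite(diag(r)) | diag(cw$cov) < .Machine$double.eps)
  r[!is.finite(r)] <- 0
  if (length(bad)) {
    r[bad, ] <- 0; r[, bad] <- 0
  }
  z <- .fisher_z(r)
  .connectivity_object(z, condition, bad)
}

#' Resting functional connectivity
#'
#' Unweighted Pearson correlation across the concatenated resting runs,
#' Fisher-transformed with clipping. Constant parcels are flagged and zeroed.
#'
#' @param rest_timeseries list of time x parcel run matrices (or one matrix).
#' @return `wmo_connectivity` with condition `"rest"`.
#' @export
rest_connectivity <- function(rest_timeseries) {
  if (is.matrix(rest_timeseries)) rest_timeseries <- list(rest_timeseries)
  y <- do.call(rbind, rest_timeseries)
  if (nrow(y) < 3L) stop("need at least 3 time points")
  r <- .fast_cor(y)
  bad <- which(is.na(diag(r)))
  r[is.na(r)] <- 0
  if (length(bad)) {
    r[bad, ] <- 0; r[, bad] <- 0
  }
  z <- .fisher_z(r)
  .connectivity_object(z, "rest", bad)
}

#' Per-operation weighted connectivity for one subject
#'
#' Builds the rectified HRF-convolved weight series from the subject's trial
#' schedule and computes one weighted connectivity matrix per operation from
#' the task time series.
#'
#' @param subject a `wmo_subject`.
#' @param tr_seconds repetition time (default taken from the schedule's
#'   seconds columns if present, else 0.46).
#' @return named list of `wmo_connectivity`, one per operation.
#' @export
subject_task_connectivity <- function(subject, tr_seconds = 0.46) {
  w <- build_operation_weights(subject$schedule, tr_seconds,
                               nrow(subject$task_timeseries))
  out <- lapply(colnames(w), function(op) {
    weighted_connectivity(subject$task_timeseries, w[, op], condition = op)
  })
  names(out) <- colnames(w)
  out
}
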