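#' Parcel eccentricity in gradient space
#'
#' Euclidean distance of every parcel from the center of the gradient
#' coordinate system. By default the center is the grand mean over all
#' parcels (per subject and condition); `center_mode = "origin"` uses the raw
#' origin instead.
#'
#' @param coords parcel x component coordinate matrix.
#' @param center_mode `"grand_mean"` (default) or `"origin"`.
#' @return numeric vector of distances, one per parcel.
#' @export
parcel_eccentricity <- function(coords, center_mode = c("grand_mean", "origin")) {
  center_mode <- match.arg(center_mode)
  x <- as.matrix(coords)
  if (!all(is.finite(x))) stop("coordinates must be finite")
  center <- if (center_mode == "grand_mean") colMeans(x) else rep(0, ncol(x))
  sqrt(rowSums(sweep(x, 2L, center, "-")^2))
}

#' Network eccentricity (member mean)
#'
#' @param parcel_distances vector from [parcel_eccentricity()].
#' @param network_labels factor of network labels, one per parcel.
#' @return named numeric vector of per-network mean eccentricities.
#' @export
network_eccentricity <- function(parcel_distances, network_labels) {
  labels <- if (is.factor(network_labels)) network_labels else factor(network_labels)
  if (length(parcel_distances) != length(labels) || anyNA(labels)) {
    stop("every parcel needs a network label")
  }
  counts <- table(labels)
  if (any(counts == 0L)) {
    stop(sprintf("empty network(s): %s",
                 paste(names(counts)[counts == 0L], collapse = ", ")))
  }
  tapply(parcel_distances, labels, mean)
}

#' Within-network dispersion (summed Mahalanobis distance)
#'
#' Centroid = coordinate-wise median of the network's member parcels;
#' covariance = sample covariance of member coordinates with shrinkage
#' `(1 - gamma) * S + gamma * tr(S)/k * I`; dispersion = sum over members of
#' the Mahalanobis distance from the centroid. The sum (not the mean) is
#' reported, so the value scales with network size; set `per_parcel = TRUE`
#' for the mean variant.
#'
#' @param coords parcel x component coordinate matrix.
#' @param network_labels factor of network labels, one per parcel.
#' @param network network to evaluate.
#' @param shrinkage shrinkage weight gamma (default 0.05).
#' @param per_parcel if `TRUE` return the mean distance instead of the sum.
#' @return single nonnegative number.
#' @export
within_network_dispersion <- function(coords, network_labels, network,
                                      shrinkage = 0.05, per_parcel = FALSE) {
  x <- as.matrix(coords)
  labels <- factor(network_labels)
  member <- x[labels == network, , drop = FALSE]
  if (nrow(member) < 5L) stop("network needs at least 5 parcels for a stable covariance")
  centroid <- apply(member, 2L, stats::median)
  s <- stats::cov(member)
  k <- ncol(member)
  s_shrunk <- (1 - shrinkage) * s + shrinkage * sum(diag(s)) / k * diag(k)
  if (sum(diag(s)) < .Machine$double.eps) {
    # degenerate cloud (all parcels coincident): every distance is zero
    return(0)
  }
  if (rcond(s_shrunk) < .Machine$double.eps * 100) {
    stop("member covariance is singular even after shrinkage")
  }
  d2 <- stats::mahalanobis(member, centroid, s_shrunk)
  d <- sqrt(pmax(d2, 0))
  if (per_parcel) mean(d) else sum(d)
}

#' Eccentricity and dispersion table for a set of gradient solutions
#'
#' Builds the tidy subject x condition x network table of both metrics from a
#' nested list of aligned gradient sets.
#'
#' @param gradient_sets nested list: `gradient_sets[[subject]][[condition]]`
#'   of `wmo_gradients` (or plain coordinate matrices).
#' @param network_labels factor of network labels, one per parcel.
#' @param family label for the matrix family (e.g. `"rsa"`, `"fc"`,
#'   `"rest_rsa"`); recycled into the table.
#' @param center_mode,shrinkage passed to the metric functions.
#' @return data.frame with columns subject, family, condition, network,
#'   eccentricity, dispersion.
#' @export
network_metric_table <- function(gradient_sets, network_labels, family = "rsa",
                                 center_mode = "grand_mean", shrinkage = 0.05) {
  labels <- factor(network_labels)
  rows <- list()
  for (subj in names(gradient_sets)) {
    for (cond in names(gradient_sets[[subj]])) {
      g <- gradient_sets[[subj]][[cond]]
      coords <- if (inherits(g, "wmo_gradients")) g$coordinates else as.matrix(g)
      ecc <- network_eccentricity(parcel_eccentricity(coords, center_mode), labels)
      disp <- vapply(levels(labels), function(nw) {
        within_network_dispersion(coords, labels, nw, shrinkage = shrinkage)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj, family = family, condition = cond,
        network = levels(labels), eccentricity = as.numeric(ecc),
        dispersion = disp, row.names = NULL
      )
    }
  }
  do.call(rbind, rows)
}
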