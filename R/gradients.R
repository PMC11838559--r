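#' Row-wise top-fraction thresholding
#'
#' Keeps, in every row, the `k = ceiling(fraction * (n - 1))` largest
#' off-diagonal entries (ties broken toward the lower column index) and zeroes
#' the rest; the diagonal is retained. The result is generally asymmetric;
#' symmetry is restored by the subsequent row-cosine step.
#'
#' @param matrix square numeric matrix.
#' @param fraction fraction of connections to retain per row (default 0.10).
#' @return thresholded matrix of the same shape.
#' @export
threshold_top_fraction <- function(matrix, fraction = 0.10) {
  m <- as.matrix(matrix)
  n <- nrow(m)
  if (n != ncol(m)) stop("input must be square")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- ceiling(fraction * (n - 1L))
  out <- base::matrix(0, n, n, dimnames = dimnames(m))
  cols <- seq_len(n)
  for (i in seq_len(n)) {
    row <- m[i, ]
    off <- cols[cols != i]
    ord <- off[order(-row[off], off)]
    keep <- ord[seq_len(min(k, length(ord)))]
    out[i, keep] <- row[keep]
    out[i, i] <- row[i]
  }
  out
}

#' Normalized-angle affinity from row profiles
#'
#' Cosine similarity between every pair of rows, mapped to
#' `1 - acos(clip(c, -1, 1)) / pi`, giving affinities in \[0, 1\] with unit
#' diagonal (identical rows 1, orthogonal rows 0.5, antipodal rows 0).
#'
#' @param thresholded_matrix square matrix (typically top-fraction
#'   thresholded).
#' @return square symmetric affinity matrix.
#' @export
normalized_angle_affinity <- function(thresholded_matrix) {
  m <- as.matrix(thresholded_matrix)
  norms <- sqrt(rowSums(m^2))
  zero <- which(norms < .Machine$double.eps)
  if (length(zero)) {
    stop(sprintf("all-zero row(s) after thresholding: %s",
                 paste(zero, collapse = ", ")))
  }
  u <- m / norms
  cosine <- .clip(tcrossprod(u), -1, 1)
  a <- 1 - acos(cosine) / pi
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

#' @keywords internal
#' @noRd
.graph_connected <- function(a) {
  n <- nrow(a)
  adj <- a > 0
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    nb <- which(adj[i, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' @keywords internal
#' @noRd
.gradient_set <- function(coordinates, eigenvalues, variance_explained,
                          aligned = FALSE, template_id = NA_character_,
                          residual = NA_real_) {
  colnames(coordinates) <- paste0("g", seq_len(ncol(coordinates)))
  structure(list(coordinates = coordinates, eigenvalues = eigenvalues,
                 variance_explained = variance_explained, aligned = aligned,
                 template_id = template_id, residual = residual),
            class = "wmo_gradients")
}

#' @export
print.wmo_gradients <- function(x, ...) {
  cat(sprintf("<wmo_gradients: %d parcels x %d components, var explained %s%s>\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.2f", x$variance_explained), collapse = "/"),
              if (x$aligned) ", aligned" else ""))
  invisible(x)
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Anisotropic normalization `W' = D^-a W D^-a`, random-walk operator
#' `P = D'^-1 W'` (eigendecomposed through its symmetric conjugate), the
#' trivial constant eigenvector dropped, and the next `n_components`
#' eigenvectors returned as gradients. With `diffusion_time = 0` coordinates
#' are scaled by `lambda / (1 - lambda)` (automatic time); otherwise by
#' `lambda^t`. Variance explained is each retained eigenvalue over the sum of
#' positive nontrivial eigenvalues. Signs are fixed so each gradient's
#' largest-magnitude loading is positive.
#'
#' @param affinity symmetric nonnegative square matrix.
#' @param n_components number of gradients (default 3).
#' @param alpha anisotropic diffusion parameter (default 0.5).
#' @param diffusion_time diffusion time t (default 0 = automatic).
#' @return `wmo_gradients` with coordinates, eigenvalues and variance
#'   explained.
#' @export
diffusion_map_embed <- function(affinity, n_components = 3L, alpha = 0.5,
                                diffusion_time = 0) {
  a <- as.matrix(affinity)
  n <- nrow(a)
  if (n != ncol(a)) stop("affinity must be square")
  if (any(a < 0)) stop("affinity must be nonnegative")
  if (max(abs(a - t(a))) > 1e-8) stop("affinity must be symmetric")
  if (!.graph_connected(a)) {
    stop("affinity graph is disconnected; consider a lower threshold fraction")
  }
  d <- rowSums(a)
  w <- a / outer(d^alpha, d^alpha)
  d2 <- rowSums(w)
  s <- w / outer(sqrt(d2), sqrt(d2))
  s <- (s + t(s)) / 2
  es <- eigen(s, symmetric = TRUE)
  lam <- es$values
  # right eigenvectors of the random-walk operator, normalized so the trivial
  # (first) eigenvector is the constant 1 vector
  psi <- es$vectors / es$vectors[, 1L]
  lam_nt <- lam[-1L]
  pos <- lam_nt[lam_nt > 0]
  idx <- 1L + seq_len(n_components)
  lam_k <- lam[idx]
  scaling <- if (diffusion_time == 0) lam_k / (1 - lam_k) else lam_k^diffusion_time
  coords <- sweep(psi[, idx, drop = FALSE], 2L, scaling, "*")
  for (j in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, j])), j] < 0) coords[, j] <- -coords[, j]
  }
  .gradient_set(coords, lam_k, lam_k / sum(pos))
}

#' Mark a gradient solution valid if enough variance is explained
#'
#' The retained components should account for more than a floor fraction of
#' the nontrivial eigenvalue mass (the usual rule justifying keeping
#' three gradients, over 50 percent).
#'
#' @param gradient_set `wmo_gradients`.
#' @param floor minimum summed variance explained (default 0.5).
#' @return the gradient set with a logical `valid` field set.
#' @export
check_variance_floor <- function(gradient_set, floor = 0.5) {
  gradient_set$valid <- sum(gradient_set$variance_explained) >= floor
  gradient_set
}

#' Group template embedding
#'
#' Embeds the element-wise mean of the supplied affinity matrices (across
#' subjects and conditions); this embedding is the alignment target for every
#' individual solution.
#'
#' @param all_subject_affinities list of same-shape affinity matrices.
#' @param ... passed to [diffusion_map_embed()].
#' @return `wmo_gradients` with `template_id = "group-mean"`.
#' @export
build_group_template <- function(all_subject_affinities, ...) {
  if (!length(all_subject_affinities)) stop("no affinities supplied")
  dims <- vapply(all_subject_affinities, function(m) dim(as.matrix(m)), integer(2))
  if (any(dims != dims[, 1])) stop("affinity shapes differ across subjects")
  mean_aff <- Reduce(`+`, lapply(all_subject_affinities, as.matrix)) /
    length(all_subject_affinities)
  g <- diffusion_map_embed(mean_aff, ...)
  g$template_id <- "group-mean"
  g
}

#' Procrustes alignment of a gradient set to a template
#'
#' Orthogonal rotation (reflections allowed, no scaling) of the subject
#' coordinates onto the template coordinates, minimizing the Frobenius
#' residual. Orthogonality makes the map an isometry, so eccentricity and
#' dispersion are unchanged by alignment.
#'
#' @param gradient_set `wmo_gradients` to align.
#' @param template `wmo_gradients` with the same parcel and component count.
#' @return aligned `wmo_gradients` with the residual recorded.
#' @export
align_to_template <- function(gradient_set, template) {
  x <- gradient_set$coordinates
  y <- template$coordinates
  if (!all(dim(x) == dim(y))) stop("parcel/component counts differ from template")
  m <- crossprod(x, y)
  sv <- svd(m)
  if (max(sv$d) <= 0 || min(sv$d) < .Machine$double.eps * max(sv$d) * nrow(m)) {
    stop("cross-product is rank deficient; alignment is not identified")
  }
  rot <- sv$u %*% t(sv$v)
  aligned <- x %*% rot
  out <- gradient_set
  out$coordinates <- aligned
  colnames(out$coordinates) <- colnames(x)
  out$aligned <- TRUE
  out$template_id <- template$template_id
  out$residual <- sqrt(sum((aligned - y)^2))
  out$rotation <- rot
  out
}

#' Full matrix-to-aligned-gradients step
#'
#' Threshold, normalized-angle affinity, diffusion-map embedding, and
#' (optionally) Procrustes alignment in one call.
#'
#' @param matrix square similarity/connectivity matrix.
#' @param template optional `wmo_gradients` alignment target.
#' @param top_fraction threshold fraction (default 0.10).
#' @param n_components number of gradients (default 3).
#' @param ... passed to [diffusion_map_embed()].
#' @return `wmo_gradients`.
#' @export
gradients_from_matrix <- function(matrix, template = NULL, top_fraction = 0.10,
                                  n_components = 3L, ...) {
  if (inherits(matrix, "wmo_similarity")) matrix <- matrix$values
  if (inherits(matrix, "wmo_connectivity")) matrix <- matrix$values
  thr <- threshold_top_fraction(matrix, top_fraction)
  aff <- normalized_angle_affinity(thr)
  g <- diffusion_map_embed(aff, n_components = n_components, ...)
  if (!is.null(template)) g <- align_to_template(g, template)
  g
}

#' Affinity matrix from a similarity/connectivity matrix
#'
#' @param matrix square matrix (or `wmo_similarity` / `wmo_connectivity`).
#' @param top_fraction threshold fraction (default 0.10).
#' @return normalized-angle affinity matrix.
#' @export
affinity_from_matrix <- function(matrix, top_fraction = 0.10) {
  if (inherits(matrix, "wmo_similarity")) matrix <- matrix$values
  if (inherits(matrix, "wmo_connectivity")) matrix <- matrix$values
  normalized_angle_affinity(threshold_top_fraction(matrix, top_fraction))
}
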