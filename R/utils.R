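# internal numerical helpers shared across modules

#' @keywords internal
#' @noRd
.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Pearson correlation between the COLUMNS of x (and optionally y) computed via
# BLAS crossprod of the standardized matrix; columns with zero variance yield
# NA which callers handle explicitly.  Much faster than cor() for the wide
# matrices this package produces (trial x trial, parcel x parcel).
#' @keywords internal
#' @noRd
.fast_cor <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 observations to correlate")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  ss <- sqrt(colSums(xc^2))
  zero <- ss < .Machine$double.eps * n
  ss[zero] <- 1
  z <- sweep(xc, 2L, ss, "/")
  r <- crossprod(z)
  r <- .clip(r, -1, 1)
  if (any(zero)) {
    r[zero, ] <- NA_real_
    r[, zero] <- NA_real_
  }
  diag(r) <- ifelse(zero, NA_real_, 1)
  r
}

# strictly-lower-triangle vectorization used for second-order RSA
#' @keywords internal
#' @noRd
.lower_tri <- function(m) m[lower.tri(m, diag = FALSE)]

#' @keywords internal
#' @noRd
.check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

#' @keywords internal
#' @noRd
.operations <- c("maintain", "replace", "suppress", "clear")

#' @keywords internal
#' @noRd
.networks <- c("V", "SM", "DM", "FPC")
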