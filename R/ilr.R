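#' Isometric log-ratio (ilr) transform of a composition
#'
#' Maps a D-part composition (strictly positive, summing to 1) to D-1
#' unconstrained real coordinates using the sequential-binary-partition basis:
#' coordinate j equals `sqrt(j/(j+1)) * log(gm(x_1..x_j) / x_(j+1))`, where
#' `gm` is the geometric mean. The map is an isometry between Aitchison
#' geometry on the simplex and Euclidean geometry, which is what makes
#' ordinary multivariate tests (e.g. MANOVA) applicable to compositions.
#'
#' @param x A numeric vector (one composition) or matrix / data frame with one
#'   composition per row. Entries must be strictly positive; rows are closed
#'   (rescaled to sum to 1) first. Use [zero_replace()] beforehand if zeros
#'   are present.
#' @param basis Optional D x (D-1) orthonormal log-contrast basis matrix;
#'   defaults to the sequential-binary-partition basis from [ilr_basis()].
#' @return A matrix with D-1 columns (`ilr1`, `ilr2`, ...), one row per input
#'   composition; a single vector input returns a 1-row matrix.
#' @examples
#' ilr_transform(c(1, 1, 1) / 3) # origin
#' ilr_transform(c(0.88, 0.12)) # sqrt(1/2) * log(0.88/0.12)
#' @export
ilr_transform <- function(x, basis = NULL) {
  x <- as.matrix(if (is.null(dim(x))) t(x) else x)
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("compositions must be strictly positive; apply zero_replace() first")
  }
  d <- ncol(x)
  if (d < 2) abort("a composition needs at least 2 parts")
  x <- x / rowSums(x)
  v <- basis %||% ilr_basis(d)
  z <- log(x) %*% v
  colnames(z) <- paste0("ilr", seq_len(d - 1))
  z
}

#' Sequential-binary-partition ilr basis
#'
#' Columns are orthonormal log-contrast vectors: column j contrasts the
#' geometric mean of parts 1..j against part j+1.
#'
#' @param d Number of parts.
#' @return A d x (d-1) matrix.
#' @export
ilr_basis <- function(d) {
  v <- matrix(0, d, d - 1)
  for (j in seq_len(d - 1)) {
    v[seq_len(j), j] <- sqrt(j / (j + 1)) / j
    v[j + 1, j] <- -sqrt(j / (j + 1))
  }
  v
}

#' Inverse ilr transform
#'
#' @param z Matrix (or vector) of ilr coordinates, D-1 columns.
#' @inheritParams ilr_transform
#' @return Matrix of compositions (rows sum to 1), D columns.
#' @export
ilr_inverse <- function(z, basis = NULL) {
  z <- as.matrix(if (is.null(dim(z))) t(z) else z)
  d <- ncol(z) + 1L
  v <- basis %||% ilr_basis(d)
  x <- exp(z %*% t(v))
  x / rowSums(x)
}

#' Multiplicative zero replacement for compositions
#'
#' Replaces zero parts by a small value delta (by default 0.65 times the
#' smallest non-zero proportion observed in the whole input) and shrinks the
#' non-zero parts multiplicatively so each row still sums to 1. Standard
#' practice before log-ratio transforms, which are undefined at zero.
#'
#' @param x Matrix or data frame of compositions, one per row.
#' @param delta Replacement value; default `0.65 * min(x[x > 0])`.
#' @return Matrix of strictly positive compositions.
#' @export
zero_replace <- function(x, delta = NULL) {
  x <- as.matrix(if (is.null(dim(x))) t(x) else x)
  x <- x / rowSums(x)
  if (!any(x == 0)) return(x)
  delta <- delta %||% (0.65 * min(x[x > 0]))
  out <- t(apply(x, 1, function(r) {
    nz <- r == 0
    if (!any(nz)) return(r)
    r[nz] <- delta
    r[!nz] <- r[!nz] * (1 - sum(nz) * delta)
    r
  }))
  out / rowSums(out)
}
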