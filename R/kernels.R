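# Organization matrices: kernel functions applied to the training adjacency
# matrix.  Each column of the adjacency is treated as the feature vector of
# its node, so a kernel on those vectors yields an n x n structural "view"
# of the network that the factorization fuses with the adjacency itself.
# Kernels are always computed from the training adjacency, never the full
# network: anything else would leak test edges into the model.

new_kernel <- function(R, kind, normalized = FALSE) {
  structure(list(R = R, kind = kind, normalized = normalized),
            class = "lp_kernel")
}

#' @export
print.lp_kernel <- function(x, ...) {
  cat(sprintf("<lp_kernel> %s, %d x %d%s\n", x$kind,
              nrow(x$R), ncol(x$R),
              if (x$normalized) ", normalized to [0,1]" else ""))
  invisible(x)
}

check_square_symmetric <- function(A, tol = 1e-10) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("matrix must be square")
  if (max(abs(A - t(A))) > tol) stop("matrix must be symmetric")
  invisible(A)
}

#' Linear kernel of a training adjacency matrix
#'
#' Computes \eqn{R = A^T A}.  Because the adjacency is symmetric, the
#' off-diagonal entry \eqn{R_{ij}} is exactly the number of common
#' neighbors of i and j, and the diagonal holds node degrees: this kernel
#' captures local (neighborhood-overlap) structure.  The result is
#' symmetric positive semidefinite.
#'
#' @param A1 Square symmetric 0/1 matrix (training adjacency).
#' @return An `lp_kernel` with `kind = "linear"`.
#' @export
linear_kernel <- function(A1) {
  check_square_symmetric(A1)
  new_kernel(crossprod(A1), "linear")
}

#' Covariance kernel of a training adjacency matrix
#'
#' Treats the columns \eqn{X_{\cdot i}} of the adjacency as observations of
#' an n-dimensional feature vector and computes their sample covariance
#' \eqn{R = \frac{1}{n-1}\sum_i (X_{\cdot i}-\mu)(X_{\cdot i}-\mu)^T},
#' where \eqn{\mu} is the mean column.  This captures global
#' (whole-network co-connection) structure.  The result is symmetric
#' positive semidefinite but its entries can be negative, which is why
#' fusion applies [normalize_kernel()] by default.
#'
#' @param A1 Square symmetric 0/1 matrix with n >= 2.
#' @return An `lp_kernel` with `kind = "covariance"`.
#' @export
covariance_kernel <- function(A1) {
  check_square_symmetric(A1)
  n <- nrow(A1)
  if (n < 2L) stop("covariance kernel requires n >= 2")
  centered <- A1 - rowMeans(A1)
  new_kernel(tcrossprod(centered) / (n - 1), "covariance")
}

#' Min-max normalize a kernel matrix to \[0, 1\]
#'
#' Rescales entrywise as \eqn{R' = (R - \min R) / (\max R - \min R)}.  A
#' constant matrix maps to all zeros.  Normalization keeps the fusion
#' weights `1 + gamma * R` at or above 1 and guards against the negative
#' entries a covariance kernel can produce, which would break the
#' nonnegativity of the multiplicative-update ratios.  Idempotent on
#' already-normalized non-degenerate input.
#'
#' @param R An `lp_kernel` or a plain numeric matrix with finite entries.
#' @return Same type as the input, with entries in \[0, 1\].
#' @export
normalize_kernel <- function(R) {
  is_k <- inherits(R, "lp_kernel")
  M <- if (is_k) R$R else R
  if (any(!is.finite(M))) stop("kernel matrix has NaN/Inf entries")
  rng <- range(M)
  M <- if (rng[2] == rng[1]) M * 0 else (M - rng[1]) / (rng[2] - rng[1])
  if (is_k) new_kernel(M, R$kind, normalized = TRUE) else M
}

#' Organization matrix for fusion
#'
#' Convenience dispatcher used by the fitting front ends: computes the
#' requested kernel from the training adjacency and (by default)
#' normalizes it.
#'
#' @param A1 Training adjacency matrix.
#' @param kernel One of `"linear"`, `"covariance"`, `"none"`, or a
#'   precomputed symmetric matrix (validated).
#' @param normalize Min-max normalize to \[0, 1\] (default `TRUE`).
#' @return An n x n matrix, or `NULL` for `kernel = "none"`.
#' @export
organization_matrix <- function(A1, kernel = "linear", normalize = TRUE) {
  if (is.matrix(kernel)) {
    check_square_symmetric(kernel, tol = 1e-8)
    if (nrow(kernel) != nrow(A1)) stop("organization matrix size mismatch")
    return(if (normalize) normalize_kernel(kernel) else kernel)
  }
  kernel <- match.arg(kernel, c("linear", "covariance", "none"))
  if (kernel == "none") return(NULL)
  k <- switch(kernel, linear = linear_kernel(A1),
              covariance = covariance_kernel(A1))
  if (normalize) k <- normalize_kernel(k)
  k$R
}
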