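# Kernel-fused weighted NMF by multiplicative updates.
#
# Model: minimize over W >= 0 (n x C), H >= 0 (C x n)
#
#   O(W, H) = sum_ij (1 + gamma * R_ij) (A1_ij - (WH)_ij)^2
#             + lambda (||W||_F^2 + ||H||_F^2)
#
# where R is the organization matrix from a kernel and gamma scales its
# strength.  With Q = 1 + gamma * R the multiplicative updates are
#
#   W  <- W  * [(Q . A1) H^T]    / [(Q . (WH)) H^T   + lambda W  ]
#   H^T<- H^T* [(Q . A1^T) W]    / [(Q . (WH))^T W   + lambda H^T]
#
# (elementwise product/quotient).  These are the standard weighted
# Lee-Seung rules with Tikhonov regularization: each is a
# majorization-minimization step, so O is non-increasing and nonnegativity
# is preserved.  gamma = 0 recovers plain regularized NMF; gamma = 0,
# lambda = 0 recovers the classical Lee-Seung updates exactly.

DENOM_FLOOR <- 1e-12

#' Fit configuration for the fused NMF model
#'
#' @param C Latent dimension (inner rank); `NULL` to choose via
#'   [select_rank()] at fit time.
#' @param gamma Kernel fusion strength, >= 0 (default 0.1).
#' @param lam Tikhonov regularization weight, >= 0 (default 2).
#' @param max_iter Maximum multiplicative-update iterations (default 500).
#' @param tol Relative objective-change convergence threshold
#'   (default 1e-6).
#' @param restarts Independent random initializations; the restart with the
#'   lowest final objective wins (default 10).
#' @param seed Base RNG seed; restart r uses `seed + r - 1` (default 42).
#' @param mode `"dense"` (full loss) or `"sparse"` (loss restricted to
#'   observed training edges; per-iteration cost O(mC)).
#' @return A list of class `nmf_config`.
#' @export
nmf_config <- function(C = NULL, gamma = 0.1, lam = 2, max_iter = 500,
                       tol = 1e-6, restarts = 10, seed = 42,
                       mode = c("dense", "sparse")) {
  stopifnot(gamma >= 0, lam >= 0, max_iter >= 1, tol > 0, restarts >= 1)
  structure(list(C = C, gamma = gamma, lam = lam, max_iter = max_iter,
                 tol = tol, restarts = as.integer(restarts),
                 seed = as.integer(seed), mode = match.arg(mode)),
            class = "nmf_config")
}

#' Random nonnegative factor initialization
#'
#' Entries i.i.d. uniform on (1e-6, 1]: strictly positive, because zero
#' entries are absorbing under multiplicative updates.  Deterministic given
#' `seed`.
#'
#' @param n Matrix side (number of nodes).
#' @param C Latent dimension; `C > n` is allowed with a warning.
#' @param seed Integer RNG seed.
#' @return List with `W` (n x C) and `H` (C x n).
#' @export
init_factors <- function(n, C, seed) {
  stopifnot(n >= 1, C >= 1)
  if (C > n) warning("latent dimension C exceeds n")
  eps <- 1e-6
  with_seed(seed, {
    W <- matrix(eps + (1 - eps) * stats::runif(n * C), n, C)
    H <- matrix(eps + (1 - eps) * stats::runif(C * n), C, n)
    list(W = W, H = H)
  })
}

#' Fused weighted-NMF objective
#'
#' \eqn{\sum_{ij} (1+\gamma R_{ij})(A_{ij} - (WH)_{ij})^2 +
#' \lambda(\|W\|_F^2 + \|H\|_F^2)}.  This is the quantity the
#' multiplicative updates provably do not increase, and the one monitored
#' for convergence.
#'
#' @param A1 Training adjacency matrix.
#' @param R Organization matrix (same size as `A1`) or `NULL` for no
#'   fusion.
#' @param W,H Nonnegative factors.
#' @param gamma,lam Model parameters.
#' @return A nonnegative scalar.
#' @export
nmf_objective <- function(A1, R, W, H, gamma, lam) {
  if (min(W) < 0 || min(H) < 0) stop("factors must be nonnegative")
  Q <- if (is.null(R) || gamma == 0) 1 else 1 + gamma * R
  sum(Q * (A1 - W %*% H)^2) + lam * (sum(W^2) + sum(H^2))
}

#' One alternating multiplicative update of both factors
#'
#' Updates W (with H fixed), then H (with the new W fixed).  Denominators
#' are floored at 1e-12 to avoid 0/0.  Nonnegativity is preserved and the
#' objective does not increase.
#'
#' @inheritParams nmf_objective
#' @return List with updated `W` and `H`.
#' @export
update_factors <- function(A1, R, W, H, gamma, lam) {
  Q <- if (is.null(R) || gamma == 0) NULL else 1 + gamma * R
  QA <- if (is.null(Q)) A1 else Q * A1
  WH <- W %*% H
  QWH <- if (is.null(Q)) WH else Q * WH
  W <- W * (QA %*% t(H)) / pmax(QWH %*% t(H) + lam * W, DENOM_FLOOR)
  WH <- W %*% H
  QWH <- if (is.null(Q)) WH else Q * WH
  Ht <- t(H) * (t(QA) %*% W) / pmax(t(QWH) %*% W + lam * t(H), DENOM_FLOOR)
  list(W = W, H = t(Ht))
}

run_dense <- function(A1, R, cfg, init_seed) {
  f <- init_factors(nrow(A1), cfg$C, init_seed)
  W <- f$W; H <- f$H
  trace <- nmf_objective(A1, R, W, H, cfg$gamma, cfg$lam)
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    f <- update_factors(A1, R, W, H, cfg$gamma, cfg$lam)
    W <- f$W; H <- f$H
    obj <- nmf_objective(A1, R, W, H, cfg$gamma, cfg$lam)
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1L]
    if (abs(obj - prev) / max(prev, DENOM_FLOOR) < cfg$tol) {
      converged <- TRUE
      break
    }
  }
  list(W = W, H = H, trace = trace, converged = converged)
}

# Sparse mode: the loss sums only over observed training edges (pairs with
# A1_ij = 1, both orientations).  Per-iteration cost O(mC): (WH)_ij is
# evaluated only on the edge support, via sparse matrices.
run_sparse <- function(A1, R, cfg, init_seed) {
  n <- nrow(A1)
  idx <- which(A1 == 1, arr.ind = TRUE)       # both orientations
  ei <- idx[, 1L]; ej <- idx[, 2L]
  q <- if (is.null(R) || cfg$gamma == 0) rep(1, length(ei))
       else 1 + cfg$gamma * R[idx]
  Qs  <- Matrix::sparseMatrix(i = ei, j = ej, x = q, dims = c(n, n))
  f <- init_factors(n, cfg$C, init_seed)
  W <- f$W; H <- f$H
  sp_obj <- function(W, H) {
    wh <- rowSums(W[ei, , drop = FALSE] * t(H)[ej, , drop = FALSE])
    sum(q * (1 - wh)^2) + cfg$lam * (sum(W^2) + sum(H^2))
  }
  trace <- sp_obj(W, H)
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    wh <- rowSums(W[ei, , drop = FALSE] * t(H)[ej, , drop = FALSE])
    P <- Matrix::sparseMatrix(i = ei, j = ej, x = q * wh, dims = c(n, n))
    W <- W * as.matrix(Qs %*% t(H)) /
      pmax(as.matrix(P %*% t(H)) + cfg$lam * W, DENOM_FLOOR)
    wh <- rowSums(W[ei, , drop = FALSE] * t(H)[ej, , drop = FALSE])
    P <- Matrix::sparseMatrix(i = ei, j = ej, x = q * wh, dims = c(n, n))
    Ht <- t(H) * as.matrix(Matrix::t(Qs) %*% W) /
      pmax(as.matrix(Matrix::t(P) %*% W) + cfg$lam * t(H), DENOM_FLOOR)
    H <- t(Ht)
    obj <- sp_obj(W, H)
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1L]
    if (abs(obj - prev) / max(prev, DENOM_FLOOR) < cfg$tol) {
      converged <- TRUE
      break
    }
  }
  list(W = W, H = H, trace = trace, converged = converged)
}

#' Fit the fused weighted-NMF model
#'
#' Runs `restarts` independent multiplicative-update optimizations from
#' random initializations (restart r seeded with `seed + r - 1`), each
#' iterated until the relative objective change drops below `tol` or
#' `max_iter` is reached, and keeps the restart with the lowest final
#' objective.  Fully deterministic given the configuration.
#'
#' @param A1 Training adjacency matrix (n x n, symmetric 0/1).
#' @param R Organization matrix (n x n) or `NULL` for no fusion.
#' @param config An [nmf_config()]; if `config$C` is `NULL` the rank is
#'   chosen by [select_rank()] (capped at 50).
#' @return An `nmf_fit` object: `W`, `H`, `C`, `objective_trace` (best
#'   restart), `objective`, `converged`, `best_restart`, `config`.
#' @examples
#' net <- planted_low_rank(40, 3, seed = 1)
#' A <- to_adjacency(net)
#' fit <- nmf_fit(A, NULL, nmf_config(C = 3, gamma = 0, lam = 0,
#'                                    restarts = 2, seed = 1))
#' fit$objective / sum(A^2)  # near zero: planted structure recovered
#' @export
nmf_fit <- function(A1, R = NULL, config = nmf_config()) {
  stopifnot(inherits(config, "nmf_config"))
  if (!is.null(R) && config$gamma > 0 &&
      !identical(dim(R), dim(A1))) stop("R must have the same shape as A1")
  cfg <- config
  if (is.null(cfg$C)) cfg$C <- select_rank(A1, max_C = min(50L, nrow(A1)))
  runner <- switch(cfg$mode, dense = run_dense, sparse = run_sparse)
  best <- NULL
  for (r in seq_len(cfg$restarts)) {
    res <- runner(A1, R, cfg, cfg$seed + r - 1L)
    if (is.null(best) ||
        res$trace[length(res$trace)] < best$trace[length(best$trace)]) {
      best <- res
      best$restart <- r
    }
  }
  structure(
    list(W = best$W, H = best$H, C = cfg$C,
         objective_trace = best$trace,
         objective = best$trace[length(best$trace)],
         converged = best$converged,
         best_restart = best$restart,
         config = cfg),
    class = "nmf_fit"
  )
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf(
    "<nmf_fit> C=%d %s mode; objective %.6g after %d iterations (%s), best restart %d/%d\n",
    x$C, x$config$mode, x$objective, length(x$objective_trace) - 1L,
    if (x$converged) "converged" else "max_iter reached",
    x$best_restart, x$config$restarts))
  invisible(x)
}

#' Score candidate pairs from fitted factors
#'
#' The reconstruction `S = W %*% H` is symmetrized as `(S + t(S)) / 2` and
#' read out at the candidate pairs of the split (pairs absent from the
#' training graph); training edges are never ranked.
#'
#' @param fit An `nmf_fit`.
#' @param split An `lp_split` with matching dimension.
#' @param method Label recorded in the score table.
#' @return An `lp_scores` data.frame; see [score_table()].
#' @export
predict_scores <- function(fit, split, method = "nmf") {
  stopifnot(inherits(fit, "nmf_fit"), is_split(split))
  if (nrow(fit$W) != split$n) stop("factor/split dimension mismatch")
  S <- fit$W %*% fit$H
  S <- (S + t(S)) / 2
  cand <- candidate_pairs(split)
  score_table(split, S[cand], method, cand)
}

#' Choose the latent dimension from the spectrum
#'
#' Returns the smallest C whose top-C singular values capture at least
#' `energy` (default 90%) of the squared Frobenius norm of `A1`, capped at
#' `max_C`.  A pragmatic stand-in for more elaborate rank-selection
#' schemes: adjacency spectra of structured graphs concentrate their
#' energy in few components, while noise spreads it, hitting the cap.
#'
#' @param A1 Training adjacency matrix.
#' @param max_C Upper bound on the returned rank.
#' @param energy Fraction of squared-Frobenius energy to capture.
#' @return An integer in `[1, max_C]`.
#' @export
select_rank <- function(A1, max_C = 50L, energy = 0.9) {
  stopifnot(max_C >= 1)
  max_C <- min(max_C, nrow(A1))
  d2 <- svd(A1, nu = 0, nv = 0)$d^2
  tot <- sum(d2)
  if (tot == 0) return(1L)
  C <- which(cumsum(d2) / tot >= energy)[1L]
  if (is.na(C)) C <- max_C
  as.integer(min(C, max_C))
}
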