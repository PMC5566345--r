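# Seeded synthetic-network generators.  Every generator isolates its RNG use
# (the caller's .Random.seed is saved and restored) and is deterministic per
# seed, so fixtures can be rebuilt anywhere without stored data.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

upper_pairs <- function(n) {
  j <- rep.int(seq_len(n), seq_len(n) - 1L)      # j runs 2..n
  i <- sequence(seq_len(n) - 1L)                 # i < j
  cbind(i, j)
}

#' Erdos-Renyi random graph
#'
#' Each of the n(n-1)/2 node pairs is an edge independently with
#' probability `p`.
#'
#' @param n Number of nodes (>= 2).
#' @param p Edge probability in \[0, 1\].
#' @param seed Integer RNG seed; the same seed always yields the same graph.
#' @return An `lp_network` with labels `"1"..."n"`.
#' @export
erdos_renyi <- function(n, p, seed) {
  stopifnot(n >= 2, p >= 0, p <= 1)
  pairs <- upper_pairs(n)
  on <- with_seed(seed, stats::runif(nrow(pairs)) < p)
  if (!any(on)) stop("empty graph: no edges drawn (p too small?)")
  new_network(as.character(seq_len(n)), pairs[on, , drop = FALSE])
}

#' Planted-partition (stochastic block model) graph
#'
#' Nodes are assigned to `n_blocks` near-equal contiguous blocks (sizes
#' differ by at most 1); within-block pairs are edges with probability
#' `p_in`, between-block pairs with probability `p_out < p_in`.  The block
#' assignment is attached as attribute `"block"` so recovery assertions can
#' reference the planted structure directly.
#'
#' @param n Number of nodes.
#' @param n_blocks Number of blocks.
#' @param p_in,p_out Within- and between-block edge probabilities,
#'   `p_in > p_out`.
#' @param seed Integer RNG seed.
#' @return An `lp_network` with attribute `block` (integer vector length n).
#' @export
planted_partition <- function(n, n_blocks, p_in, p_out, seed) {
  stopifnot(n >= 2, n_blocks >= 1, p_in > p_out, p_in <= 1, p_out >= 0)
  sizes <- diff(floor(seq(0, n, length.out = n_blocks + 1L)))
  block <- rep.int(seq_len(n_blocks), sizes)
  pairs <- upper_pairs(n)
  same <- block[pairs[, 1L]] == block[pairs[, 2L]]
  prob <- ifelse(same, p_in, p_out)
  on <- with_seed(seed, stats::runif(nrow(pairs)) < prob)
  if (!any(on)) stop("empty graph: no edges drawn")
  net <- new_network(as.character(seq_len(n)), pairs[on, , drop = FALSE])
  attr(net, "block") <- block
  net
}

#' Planted low-rank graph
#'
#' Generates a graph whose adjacency matrix admits an exact nonnegative
#' factorization of inner rank `rank`: nodes are assigned uniformly at
#' random to `rank` groups and every pair of nodes in cyclically adjacent
#' groups (group a with group a+1 mod rank) is connected.  Writing
#' \eqn{u_a} for the indicator vector of group a, the adjacency is
#' \eqn{A = \sum_a u_a u_{a+1}^T + u_{a+1} u_a^T}, which equals \eqn{W_0 H_0}
#' for the nonnegative factors \eqn{W_0 = [u_1 ... u_r]} and
#' \eqn{H_0} with rows \eqn{u_{a-1}^T + u_{a+1}^T} (rank 2: complete
#' bipartite).  A zero-loss rank-`rank` NMF solution therefore exists by
#' construction, which is what makes this fixture a recovery oracle for the
#' factorization fit.  Degenerate draws (an empty group) are re-drawn with
#' an incremented seed, up to 10 attempts.
#'
#' @param n Number of nodes.
#' @param rank Planted inner rank (number of groups, >= 2).
#' @param seed Integer RNG seed.
#' @return An `lp_network` with attributes `W0` (n x rank) and `H0`
#'   (rank x n), the planted nonnegative factors with `W0 %*% H0` equal to
#'   the adjacency matrix.
#' @export
planted_low_rank <- function(n, rank, seed) {
  stopifnot(rank >= 2, rank <= n)
  for (attempt in 0:9) {
    g <- with_seed(seed + attempt, sample.int(rank, n, replace = TRUE))
    if (length(unique(g)) == rank) {
      B <- matrix(0, rank, rank)
      a <- seq_len(rank)
      nxt <- a %% rank + 1L
      B[cbind(a, nxt)] <- 1
      B[cbind(nxt, a)] <- 1
      pairs <- upper_pairs(n)
      on <- B[cbind(g[pairs[, 1L]], g[pairs[, 2L]])] == 1
      if (!any(on) || all(on)) next
      net <- new_network(as.character(seq_len(n)), pairs[on, , drop = FALSE])
      W0 <- outer(g, a, "==") * 1
      H0 <- t(W0 %*% B)     # row z of H0 = sum of indicators of groups linked to z
      attr(net, "W0") <- W0
      attr(net, "H0") <- H0
      attr(net, "group") <- g
      return(net)
    }
  }
  stop("planted_low_rank: failed to draw a non-degenerate graph in 10 attempts")
}

#' Fixed worked toy graphs
#'
#' The small hand-checkable graphs used throughout the test suite: the path
#' P3 (1-2-3), the triangle, K4 minus one edge, and the star K1,4.
#'
#' @return A named list of `lp_network` objects:
#'   `p3`, `triangle`, `k4_minus_e`, `star`.
#' @export
toy_graphs <- function() {
  list(
    p3 = read_edge_list(c("1 2", "2 3")),
    triangle = read_edge_list(c("1 2", "2 3", "1 3")),
    k4_minus_e = read_edge_list(c("1 2", "1 3", "2 3", "2 4", "3 4")),
    star = read_edge_list(c("c a", "c b", "c d", "c e"))
  )
}
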