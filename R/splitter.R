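# Train/test edge splitting and candidate-set accounting.  The candidate set
# is every node pair absent from the training graph; it contains both the
# held-out test edges and the true non-edges, and its size satisfies
# |candidates| = n(n-1)/2 - (m - L).

#' Split a network's edges into training and test sets
#'
#' Draws `L = round(test_fraction * m)` test edges uniformly at random
#' without replacement; the rest form the training graph.  The split is
#' deterministic given `(net, test_fraction, seed)`.  No connectivity of the
#' training graph is guaranteed unless `keep_connected = TRUE`, in which
#' case splits that disconnect the training graph are re-drawn (up to
#' `max_redraws` attempts) with incremented seeds.
#'
#' @param net An `lp_network`.
#' @param test_fraction Fraction of edges held out, in (0, 1); must give
#'   `1 <= L < m`.
#' @param seed Integer RNG seed.
#' @param keep_connected Re-draw splits whose training graph is
#'   disconnected (default `FALSE`: plain uniform split).
#' @param max_redraws Attempt cap when `keep_connected = TRUE`.
#' @return An `lp_split` object: `train_adjacency` (n x n 0/1 matrix),
#'   `train_edges`, `test_edges` (index matrices, i < j), `n`, `m`, `L`,
#'   `seed`, `labels`.
#' @export
split_edges <- function(net, test_fraction, seed,
                        keep_connected = FALSE, max_redraws = 100L) {
  stopifnot(is_network(net), test_fraction > 0, test_fraction < 1)
  L <- round(test_fraction * net$m)
  if (L < 1L || L >= net$m)
    stop(sprintf("test_fraction %.3f gives L = %d with m = %d edges; need 1 <= L < m",
                 test_fraction, L, net$m))
  for (attempt in 0:max_redraws) {
    test_idx <- with_seed(seed + attempt, sample.int(net$m, L))
    train_edges <- net$edges[-test_idx, , drop = FALSE]
    if (!keep_connected) break
    g1 <- igraph::make_graph(t(train_edges), n = net$n, directed = FALSE)
    if (igraph::is_connected(g1)) break
    if (attempt == max_redraws)
      stop("split_edges: could not draw a connected training graph")
  }
  A1 <- matrix(0, net$n, net$n)
  A1[train_edges] <- 1
  A1[train_edges[, c(2L, 1L)]] <- 1
  structure(
    list(train_adjacency = A1,
         train_edges = train_edges,
         test_edges = net$edges[test_idx, , drop = FALSE],
         n = net$n, m = net$m, L = L,
         seed = seed, labels = net$labels),
    class = "lp_split"
  )
}

#' @export
print.lp_split <- function(x, ...) {
  cat(sprintf("<lp_split> n=%d m=%d L=%d (seed %d); %d candidate pairs\n",
              x$n, x$m, x$L, x$seed,
              x$n * (x$n - 1) / 2 - (x$m - x$L)))
  invisible(x)
}

is_split <- function(x) inherits(x, "lp_split")

#' Candidate pairs of a split
#'
#' All node pairs i < j absent from the training graph, in lexicographic
#' order.  The length equals `n(n-1)/2 - (m - L)`.
#'
#' @param split An `lp_split`.
#' @return An integer matrix with columns `i`, `j`.
#' @export
candidate_pairs <- function(split) {
  stopifnot(is_split(split))
  A1 <- split$train_adjacency
  idx <- which(A1 == 0 & upper.tri(A1), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  dimnames(idx) <- list(NULL, c("i", "j"))
  idx
}

#' Mark which candidate pairs are held-out test edges
#'
#' @param split An `lp_split`.
#' @param cand Candidate-pair index matrix (default: all candidates).
#' @return Logical vector parallel to the rows of `cand`.
#' @export
candidate_is_test <- function(split, cand = candidate_pairs(split)) {
  key <- function(e) (e[, 1L] - 1) * split$n + e[, 2L]
  key(cand) %in% key(split$test_edges)
}
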