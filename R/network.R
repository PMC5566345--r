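#' @keywords internal
"_PACKAGE"

# Canonical network container: labels in first-appearance order, edges as an
# m x 2 integer matrix of 1-based index pairs with i < j, sorted
# lexicographically.  All downstream modules consume this type.

new_network <- function(labels, edges) {
  n <- length(labels)
  edges <- matrix(as.integer(edges), ncol = 2L)
  # canonicalize: i < j, dedupe, lexicographic sort
  swap <- edges[, 1L] > edges[, 2L]
  edges[swap, ] <- edges[swap, c(2L, 1L)]
  edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
  edges <- unique(edges)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  if (nrow(edges) == 0L) stop("empty graph: network has no edges")
  if (min(edges) < 1L || max(edges) > n) stop("edge index out of range")
  structure(
    list(labels = as.character(labels), edges = edges,
         n = n, m = nrow(edges)),
    class = "lp_network"
  )
}

#' @export
print.lp_network <- function(x, ...) {
  cat(sprintf("<lp_network> %d nodes, %d edges\n", x$n, x$m))
  invisible(x)
}

is_network <- function(x) inherits(x, "lp_network")

#' @export
all.equal.lp_network <- function(target, current, ...) {
  # Graph equality: same label set and same edge set as label pairs.  The
  # internal index assignment depends on the order edges were listed, which
  # an edge-list file cannot preserve, so equality must not depend on it.
  if (!is_network(current)) return("current is not an lp_network")
  pairs <- function(net) {
    a <- net$labels[net$edges[, 1L]]
    b <- net$labels[net$edges[, 2L]]
    sort(paste(pmin(a, b), pmax(a, b)))
  }
  msg <- NULL
  if (target$n != current$n) msg <- c(msg, "node counts differ")
  if (!setequal(target$labels, current$labels))
    msg <- c(msg, "label sets differ")
  if (!identical(pairs(target), pairs(current)))
    msg <- c(msg, "edge sets differ")
  if (is.null(msg)) TRUE else msg
}

#' Read an undirected simple network from an edge list
#'
#' Parses a whitespace-delimited edge list (two node identifiers per line).
#' Directed duplicates are merged, multi-edges collapsed and self-loops
#' dropped, so the result is always a simple undirected graph.  Node labels
#' are arbitrary strings and are mapped to integer indices in order of first
#' appearance, giving a deterministic canonical form.
#'
#' @param source Path to a file, a connection, or a character vector of lines.
#' @param comment_prefix Lines starting with this prefix are skipped
#'   (default `"#"`); blank lines are always skipped.
#' @return An `lp_network` object with fields `labels`, `edges` (m x 2
#'   integer matrix, i < j, lexicographic), `n`, `m`.
#' @examples
#' net <- read_edge_list(c("a b", "b a", "b b", "b c"))
#' net$m  # 2: the reverse duplicate and the self-loop are dropped
#' @export
read_edge_list <- function(source, comment_prefix = "#") {
  lines <- if (is.character(source) && length(source) > 1L) source
           else if (is.character(source) && !file.exists(source)) {
             # single string that is not a path: treat as one line
             source
           } else readLines(source)
  keep <- !grepl("^\\s*$", lines) & !startsWith(trimws(lines), comment_prefix)
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty graph: no edge lines in input")
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad) > 0L)
    stop(sprintf("parse error at line %d: expected two node identifiers",
                 idx[bad[1L]]))
  ends <- vapply(toks, function(t) t[1:2], character(2L))
  labels <- unique(as.vector(ends))          # first-appearance order
  i <- match(ends[1L, ], labels)
  j <- match(ends[2L, ], labels)
  keep_edge <- i != j
  if (!any(keep_edge)) stop("empty graph: only self-loops in input")
  new_network(labels, cbind(i[keep_edge], j[keep_edge]))
}

#' Write a network as a sorted edge list
#'
#' One `label_i label_j` line per edge with i < j by canonical index, in
#' lexicographic index order, so `read_edge_list(write_edge_list(net))`
#' reproduces `net` exactly.
#'
#' @param net An `lp_network`.
#' @param sink File path or connection.
#' @return Invisibly, the character vector of lines written.
#' @export
write_edge_list <- function(net, sink) {
  stopifnot(is_network(net))
  if (net$m == 0L) stop("empty graph is not representable as an edge list")
  lines <- paste(net$labels[net$edges[, 1L]], net$labels[net$edges[, 2L]])
  writeLines(lines, sink)
  invisible(lines)
}

#' Adjacency matrix of a network
#'
#' @param net An `lp_network`.
#' @return An n x n symmetric 0/1 matrix with zero diagonal; its entry sum
#'   is 2m.  Row/column names carry the node labels.
#' @export
to_adjacency <- function(net) {
  stopifnot(is_network(net))
  A <- matrix(0, net$n, net$n, dimnames = list(net$labels, net$labels))
  A[net$edges] <- 1
  A[net$edges[, c(2L, 1L)]] <- 1
  A
}

as_igraph <- function(net) {
  igraph::make_graph(t(net$edges), n = net$n, directed = FALSE)
}

#' Topological summary statistics of a network
#'
#' Computes the standard descriptors used in network-dataset summary tables:
#' node and edge counts, average degree \eqn{\langle k\rangle}, clustering
#' coefficient (mean local clustering, nodes of degree < 2 contributing 0),
#' average shortest-path distance over reachable pairs, degree heterogeneity
#' \eqn{H = \langle k^2\rangle / \langle k\rangle^2} and degree assortativity
#' (Pearson degree--degree correlation over edges; 0 is reported for regular
#' graphs, where the correlation is undefined).
#'
#' @param net An `lp_network` with at least 2 nodes.
#' @return A one-row data.frame with columns `n`, `m`, `avg_degree`,
#'   `clustering_coefficient`, `avg_shortest_distance`, `heterogeneity`,
#'   `assortativity`.
#' @examples
#' tri <- read_edge_list(c("1 2", "2 3", "1 3"))
#' network_stats(tri)  # <k> = 2, CC = 1, <d> = 1, H = 1
#' @export
network_stats <- function(net) {
  stopifnot(is_network(net))
  if (net$n < 2L) stop("network_stats requires at least 2 nodes")
  g <- as_igraph(net)
  k <- igraph::degree(g)
  cc_local <- igraph::transitivity(g, type = "localundirected",
                                   isolates = "zero")
  cc_local[is.na(cc_local)] <- 0   # degree-1 nodes
  r <- suppressWarnings(igraph::assortativity_degree(g))
  if (!is.finite(r)) r <- 0        # regular graph: zero degree variance
  data.frame(
    n = net$n, m = net$m,
    avg_degree = 2 * net$m / net$n,
    clustering_coefficient = mean(cc_local),
    avg_shortest_distance = igraph::mean_distance(g, unconnected = TRUE),
    heterogeneity = mean(k^2) / mean(k)^2,
    assortativity = r
  )
}
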