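# Classical similarity indices for link prediction, all computed from the
# TRAINING graph only.  With Gamma(x) the training neighborhood of x and
# k_x its training degree:
#
#   CN      = |Gamma(x) n Gamma(y)|
#   AA      = sum_z 1 / log k_z           (z a common neighbor; natural log)
#   RA      = sum_z 1 / k_z
#   Salton  = CN / sqrt(k_x k_y)
#   Jaccard = |Gamma(x) n Gamma(y)| / |Gamma(x) u Gamma(y)|
#   CRA     = sum_z alpha_z / k_z,  alpha_z = |Gamma(z) n Gamma(x) n Gamma(y)|
#   ACT     = 1 / (l+_xx + l+_yy - 2 l+_xy),  L+ = pinv of the Laplacian
#
# Degenerate guards: Salton and Jaccard are 0 when their denominator is 0
# (then CN is necessarily 0 too); ACT is 0 when the commute-time
# denominator is <= 1e-12.

#' Build a deterministic candidate-pair score table
#'
#' Orders rows by score descending, ties broken by lexicographic node-index
#' pair, so rankings (and precision-at-L) are reproducible.
#'
#' @param split An `lp_split`.
#' @param scores Numeric vector parallel to `cand`.
#' @param method Method label.
#' @param cand Candidate-pair index matrix (default: all candidates).
#' @return A data.frame of class `lp_scores` with columns `node_i`,
#'   `node_j` (labels), `i`, `j` (indices), `score`, `is_test`.
#' @export
score_table <- function(split, scores, method,
                        cand = candidate_pairs(split)) {
  stopifnot(is_split(split), length(scores) == nrow(cand))
  if (any(!is.finite(scores))) stop("scores must be finite")
  ord <- order(-scores, cand[, 1L], cand[, 2L])
  out <- data.frame(
    node_i = split$labels[cand[ord, 1L]],
    node_j = split$labels[cand[ord, 2L]],
    i = cand[ord, 1L], j = cand[ord, 2L],
    score = scores[ord],
    is_test = candidate_is_test(split, cand)[ord],
    stringsAsFactors = FALSE
  )
  attr(out, "method") <- method
  class(out) <- c("lp_scores", "data.frame")
  out
}

#' Local similarity indices over the candidate set
#'
#' Computes one of the neighborhood-overlap indices (CN, AA, RA, Salton,
#' Jaccard, CRA) for every candidate pair, using the training graph only.
#'
#' @param split An `lp_split`.
#' @param index One of `"cn"`, `"aa"`, `"ra"`, `"salton"`, `"jaccard"`,
#'   `"cra"`.
#' @return An `lp_scores` table.
#' @examples
#' net <- toy_graphs()$triangle
#' sp <- split_edges(net, 1/3, seed = 1)
#' local_similarity_scores(sp, "cn")
#' @export
local_similarity_scores <- function(split,
    index = c("cn", "aa", "ra", "salton", "jaccard", "cra")) {
  stopifnot(is_split(split))
  index <- match.arg(index)
  A1 <- split$train_adjacency
  k <- colSums(A1)
  cand <- candidate_pairs(split)
  s <- switch(index,
    cn = (A1 %*% A1)[cand],
    aa = {
      w <- ifelse(k >= 2, 1 / log(k), 0)  # common neighbors have k >= 2
      (A1 %*% (w * A1))[cand]
    },
    ra = {
      w <- ifelse(k > 0, 1 / k, 0)
      (A1 %*% (w * A1))[cand]
    },
    salton = {
      cn <- (A1 %*% A1)[cand]
      den <- sqrt(k[cand[, 1L]] * k[cand[, 2L]])
      ifelse(den > 0, cn / den, 0)
    },
    jaccard = {
      cn <- (A1 %*% A1)[cand]
      un <- k[cand[, 1L]] + k[cand[, 2L]] - cn
      ifelse(un > 0, cn / un, 0)
    },
    cra = {
      vapply(seq_len(nrow(cand)), function(r) {
        z <- which(A1[cand[r, 1L], ] == 1 & A1[cand[r, 2L], ] == 1)
        if (length(z) == 0L) return(0)
        alpha <- rowSums(A1[z, z, drop = FALSE])
        sum(alpha / k[z])
      }, numeric(1L))
    }
  )
  score_table(split, as.numeric(s), index, cand)
}

#' Average-commute-time similarity over the candidate set
#'
#' Scores pairs by the reciprocal of `l+_xx + l+_yy - 2 l+_xy`, where `L+`
#' is the Moore-Penrose pseudo-inverse of the training-graph Laplacian
#' `L = D - A1`.  That quantity is the effective resistance between x and
#' y, proportional to their average commute time, so closer pairs (in the
#' random-walk sense) score higher.  Dense pseudo-inversion is used, so the
#' method refuses graphs with more than 3000 nodes; use local indices
#' there.
#'
#' @param split An `lp_split` with `n <= 3000`.
#' @return An `lp_scores` table with method `"act"`.
#' @export
act_scores <- function(split) {
  stopifnot(is_split(split))
  if (split$n > 3000L)
    stop("act_scores uses a dense pseudo-inverse; n > 3000 not supported")
  A1 <- split$train_adjacency
  L <- diag(colSums(A1)) - A1
  Lp <- MASS::ginv(L)
  d <- diag(Lp)
  cand <- candidate_pairs(split)
  den <- d[cand[, 1L]] + d[cand[, 2L]] - 2 * Lp[cand]
  s <- ifelse(den > 1e-12, 1 / den, 0)
  score_table(split, s, "act", cand)
}
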