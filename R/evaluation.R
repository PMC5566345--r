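# Evaluation metrics for a ranked candidate set: AUC (probability that a
# random test edge outranks a random non-edge, ties counting 0.5),
# precision at L (fraction of the top-L ranked candidates that are test
# edges), and prediction power, the log10 ratio of precision to the
# expected precision of a uniformly random ranking.

split_score_groups <- function(scores, split) {
  stopifnot(inherits(scores, "lp_scores"), is_split(split))
  pos <- scores$score[scores$is_test]
  neg <- scores$score[!scores$is_test]
  if (length(pos) == 0L) stop("candidate set contains no test edges")
  if (length(neg) == 0L) stop("candidate set contains no non-edges")
  list(pos = pos, neg = neg)
}

#' Exact AUC over all test-edge / non-edge pairs
#'
#' Mann-Whitney statistic: the fraction of (test edge, non-edge) candidate
#' pairs where the test edge scores strictly higher, plus half the tied
#' fraction.  This is the deterministic limit of [auc_sampled()].
#'
#' @param scores An `lp_scores` table.
#' @param split The `lp_split` the scores were computed on.
#' @return AUC in \[0, 1\].
#' @export
auc_exact <- function(scores, split) {
  g <- split_score_groups(scores, split)
  np <- length(g$pos); nn <- length(g$neg)
  r <- rank(c(g$pos, g$neg))        # midranks handle ties as 0.5
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Sampled AUC by random comparisons
#'
#' Draws `t` independent (test edge, non-edge) score pairs uniformly with
#' replacement and returns `(t' + 0.5 t'') / t`, where `t'` counts strict
#' wins for the test edge and `t''` counts ties.
#'
#' @param scores An `lp_scores` table.
#' @param split The matching `lp_split`.
#' @param t Number of comparisons (default 100000).
#' @param seed Integer RNG seed.
#' @return AUC estimate in \[0, 1\]; converges to [auc_exact()] as `t`
#'   grows.
#' @export
auc_sampled <- function(scores, split, t = 100000L, seed = 1L) {
  stopifnot(t >= 1)
  g <- split_score_groups(scores, split)
  with_seed(seed, {
    sp <- g$pos[sample.int(length(g$pos), t, replace = TRUE)]
    sn <- g$neg[sample.int(length(g$neg), t, replace = TRUE)]
    mean((sp > sn) + 0.5 * (sp == sn))
  })
}

#' Precision at L
#'
#' Fraction of the top-`L` candidates (by the table's deterministic
#' ranking: score descending, lexicographic pair tie-break) that are
#' held-out test edges.
#'
#' @param scores An `lp_scores` table (already ranked).
#' @param split The matching `lp_split`.
#' @param L Cutoff; defaults to the number of test edges.
#' @return Precision in \[0, 1\]; `precision * L` is an integer hit count.
#' @export
precision_at_L <- function(scores, split, L = split$L) {
  stopifnot(inherits(scores, "lp_scores"), is_split(split))
  if (L < 1L) stop("L must be >= 1")
  if (nrow(scores) < L) stop("candidate set smaller than L")
  sum(scores$is_test[seq_len(L)]) / L
}

#' Expected precision of a uniformly random ranking
#'
#' `L / (n(n-1)/2 - (m - L))`: L test edges among all candidates.
#'
#' @param n,m,L Node count, edge count, test-edge count.
#' @return Expected random precision in (0, 1].
#' @export
random_precision <- function(n, m, L) {
  den <- n * (n - 1) / 2 - (m - L)
  if (den <= 0) stop("candidate count must be positive")
  L / den
}

#' Prediction power
#'
#' `log10(precision / rand_prec)`: orders of magnitude by which a method
#' beats random ranking.  Zero precision yields `-Inf` with a warning
#' (kept as a sentinel rather than dropped).
#'
#' @param precision Observed precision.
#' @param rand_prec Random-ranking precision, > 0.
#' @return A real number, possibly `-Inf`.
#' @export
prediction_power <- function(precision, rand_prec) {
  if (rand_prec <= 0) stop("rand_prec must be positive")
  if (precision == 0) {
    warning("zero precision: prediction power is -Inf")
    return(-Inf)
  }
  log10(precision / rand_prec)
}

#' Evaluate a score table on a split
#'
#' Convenience wrapper computing exact AUC, precision at L and prediction
#' power in one row.
#'
#' @param scores An `lp_scores` table.
#' @param split The matching `lp_split`.
#' @return One-row data.frame: `method`, `split_seed`, `auc`, `precision`,
#'   `prediction_power`.
#' @export
evaluate_scores <- function(scores, split) {
  prec <- precision_at_L(scores, split)
  pp <- suppressWarnings(
    prediction_power(prec, random_precision(split$n, split$m, split$L)))
  data.frame(
    method = attr(scores, "method") %||% "unknown",
    split_seed = split$seed,
    auc = auc_exact(scores, split),
    precision = prec,
    prediction_power = pp,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
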