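# Repeated-split experiment driver.  Each repeat draws one split (seed =
# base_seed + repeat - 1) that is shared by every method, so method
# comparisons are paired; per-cell results are aggregated as mean and
# population standard deviation over repeats.

LP_METHODS <- c("cn", "aa", "ra", "salton", "jaccard", "cra", "act",
                "nmf3-linear", "nmf3-covariance", "nmf3-none")

#' Score a split with a named method
#'
#' Dispatcher used by [run_experiment()] and the command-line interface.
#' Method identifiers: the local indices `"cn"`, `"aa"`, `"ra"`,
#' `"salton"`, `"jaccard"`, `"cra"`; the global index `"act"`; and the
#' factorization variants `"nmf3-linear"`, `"nmf3-covariance"`,
#' `"nmf3-none"` (fusion with the linear kernel, the covariance kernel, or
#' no kernel).
#'
#' @param split An `lp_split`.
#' @param method Method identifier.
#' @param fit_config [nmf_config()] for the factorization variants.
#' @return An `lp_scores` table.
#' @export
score_method <- function(split, method, fit_config = nmf_config()) {
  if (!method %in% LP_METHODS)
    stop(sprintf("unknown method '%s'; valid: %s",
                 method, paste(LP_METHODS, collapse = ", ")))
  if (method == "act") return(act_scores(split))
  if (startsWith(method, "nmf3-")) {
    kernel <- sub("^nmf3-", "", method)
    A1 <- split$train_adjacency
    R <- organization_matrix(A1, kernel)
    fit <- nmf_fit(A1, R, fit_config)
    return(predict_scores(fit, split, method))
  }
  local_similarity_scores(split, method)
}

#' Run a repeated-split link-prediction experiment
#'
#' For every (method, training fraction, repeat) cell: split with seed
#' `base_seed + repeat - 1`, score, evaluate (exact AUC, precision at L,
#' prediction power), then aggregate mean and population standard
#' deviation per (method, fraction, metric).  Splits are shared across
#' methods within a repeat, and the whole table is deterministic given its
#' arguments.
#'
#' @param net An `lp_network`.
#' @param methods Character vector of method identifiers
#'   (see [score_method()]).
#' @param fractions Training-set fractions in (0, 1); the test fraction of
#'   each split is `1 - fraction`.
#' @param repeats Number of independent splits per cell (default 100).
#' @param base_seed Base split seed (default 42).
#' @param fit_config [nmf_config()] for factorization methods.
#' @return A data.frame with columns `method`, `fraction`, `metric`,
#'   `mean`, `std`, `repeats`.
#' @export
run_experiment <- function(net, methods, fractions = 0.9, repeats = 100L,
                           base_seed = 42L, fit_config = nmf_config()) {
  stopifnot(is_network(net), repeats >= 1,
            all(fractions > 0), all(fractions < 1))
  bad <- setdiff(methods, LP_METHODS)
  if (length(bad) > 0L)
    stop(sprintf("unknown method(s) %s; valid: %s",
                 paste(bad, collapse = ", "),
                 paste(LP_METHODS, collapse = ", ")))
  rows <- list()
  for (frac in fractions) {
    evals <- vector("list", repeats)
    for (rep_i in seq_len(repeats)) {
      split <- split_edges(net, 1 - frac, base_seed + rep_i - 1L)
      evals[[rep_i]] <- do.call(rbind, lapply(methods, function(mth)
        evaluate_scores(score_method(split, mth, fit_config), split)))
    }
    ev <- do.call(rbind, evals)
    for (mth in methods) {
      sub <- ev[ev$method == mth, ]
      for (metric in c("auc", "precision", "prediction_power")) {
        v <- sub[[metric]]
        finite <- v[is.finite(v)]   # -Inf PP sentinels skipped in means
        rows[[length(rows) + 1L]] <- data.frame(
          method = mth, fraction = frac, metric = metric,
          mean = if (length(finite)) mean(finite) else -Inf,
          std = if (length(finite)) pop_sd(finite) else NA_real_,
          repeats = repeats, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Sensitivity sweep over the fusion strength and regularization grids
#'
#' Evaluates the fused factorization at every (gamma, lambda) grid cell at
#' a fixed training fraction, averaging precision and exact AUC over
#' repeated splits (seeds `base_seed + repeat - 1`, shared across cells).
#'
#' @param net An `lp_network`.
#' @param gamma_grid,lambda_grid Non-empty numeric grids.
#' @param fraction Training fraction (default 0.9).
#' @param repeats Splits per cell (default 10).
#' @param base_seed Base split seed.
#' @param kernel Kernel for the organization matrix (default `"linear"`).
#' @param fit_config Base [nmf_config()]; its `gamma` and `lam` are
#'   overridden cell by cell.
#' @return A data.frame with columns `gamma`, `lambda`, `metric`, `mean`,
#'   `std`, `repeats`.
#' @export
parameter_sweep <- function(net, gamma_grid, lambda_grid, fraction = 0.9,
                            repeats = 10L, base_seed = 42L,
                            kernel = "linear",
                            fit_config = nmf_config()) {
  stopifnot(length(gamma_grid) >= 1, length(lambda_grid) >= 1)
  rows <- list()
  splits <- lapply(seq_len(repeats), function(r)
    split_edges(net, 1 - fraction, base_seed + r - 1L))
  Rs <- lapply(splits, function(sp)
    organization_matrix(sp$train_adjacency, kernel))
  for (gamma in gamma_grid) for (lam in lambda_grid) {
    cfg <- fit_config
    cfg$gamma <- gamma
    cfg$lam <- lam
    ev <- do.call(rbind, lapply(seq_len(repeats), function(r) {
      fit <- nmf_fit(splits[[r]]$train_adjacency, Rs[[r]], cfg)
      evaluate_scores(predict_scores(fit, splits[[r]]), splits[[r]])
    }))
    for (metric in c("auc", "precision")) {
      v <- ev[[metric]]
      rows[[length(rows) + 1L]] <- data.frame(
        gamma = gamma, lambda = lam, metric = metric,
        mean = mean(v), std = pop_sd(v), repeats = repeats,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
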