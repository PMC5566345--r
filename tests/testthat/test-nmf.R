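test_that("factor initialization is deterministic, strictly positive, mean ~ 0.5", {
  f1 <- init_factors(3, 2, seed = 7)
  f2 <- init_factors(3, 2, seed = 7)
  expect_identical(f1, f2)
  expect_true(min(f1$W) > 0 && min(f1$H) > 0)
  f <- init_factors(100, 5, seed = 1)
  expect_equal(mean(c(f$W, f$H)), 0.5, tolerance = 0.1)  # |mean-0.5| < 0.05
  expect_warning(init_factors(3, 5, seed = 1), "exceeds n")
})

test_that("objective matches scalar-loop evaluation and its closed-form corners", {
  A <- to_adjacency(toy_graphs()$k4_minus_e)
  n <- nrow(A)
  expect_equal(nmf_objective(A, NULL, matrix(0, n, 2), matrix(0, 2, n), 0, 0),
               sum(A))  # ||A||_F^2 = 2m for a 0/1 adjacency
  # exact factorization has zero loss at lambda = 0
  lr <- planted_low_rank(20, 3, seed = 1)
  W0 <- attr(lr, "W0"); H0 <- attr(lr, "H0")
  expect_equal(nmf_objective(to_adjacency(lr), NULL, W0, H0, 0, 0), 0)
  for (seed in 1:5) {
    set.seed(seed)
    A4 <- matrix(runif(16), 4); A4 <- (A4 + t(A4)) / 2
    R4 <- matrix(runif(16), 4); R4 <- (R4 + t(R4)) / 2
    W <- matrix(runif(8), 4); H <- matrix(runif(8), 2, 4)
    expect_equal(nmf_objective(A4, R4, W, H, 0.3, 1.7),
                 ref_objective(A4, R4, W, H, 0.3, 1.7), tolerance = 1e-10)
  }
  expect_error(nmf_objective(A, NULL, matrix(-1, n, 2), matrix(1, 2, n), 0, 0),
               "nonnegative")
})

test_that("unweighted unregularized updates equal the classical Lee-Seung rule", {
  for (seed in 1:6) {
    set.seed(seed)
    A <- matrix(runif(25), 5); A <- (A + t(A)) / 2
    W <- matrix(runif(15), 5, 3); H <- matrix(runif(15), 3, 5)
    got <- update_factors(A, NULL, W, H, gamma = 0, lam = 0)
    ref <- ref_leeseung_update(A, W, H)
    expect_equal(got$W, ref$W, tolerance = 1e-12)
    expect_equal(got$H, ref$H, tolerance = 1e-12)
  }
})

test_that("a single update on the 2x2 rank-1 instance matches hand arithmetic", {
  A <- matrix(c(0, 1, 1, 0), 2)
  W <- matrix(c(0.4, 0.7), 2, 1)
  H <- matrix(c(0.3, 0.9), 1, 2)
  got <- update_factors(A, NULL, W, H, gamma = 0, lam = 0)
  # W'_i = (A H^T)_i / (h1^2 + h2^2): numerators h2, h1
  h2sum <- 0.3^2 + 0.9^2
  W1 <- c(0.9 / h2sum, 0.3 / h2sum)
  expect_equal(as.vector(got$W), W1, tolerance = 1e-12)
  # H'_j = (A^T W')_j / (w1'^2 + w2'^2): numerators w2', w1'
  w2sum <- sum(W1^2)
  expect_equal(as.vector(got$H), c(W1[2] / w2sum, W1[1] / w2sum),
               tolerance = 1e-12)
})

test_that("updates preserve nonnegativity and never increase the objective", {
  net <- erdos_renyi(30, 0.15, seed = 4)
  A <- to_adjacency(net)
  R <- organization_matrix(A, "linear")
  W <- init_factors(30, 4, seed = 1)$W
  H <- init_factors(30, 4, seed = 2)$H
  obj <- nmf_objective(A, R, W, H, 0.1, 2)
  for (it in 1:50) {
    f <- update_factors(A, R, W, H, 0.1, 2)
    W <- f$W; H <- f$H
    expect_true(min(W) >= 0 && min(H) >= 0)
    obj2 <- nmf_objective(A, R, W, H, 0.1, 2)
    expect_lte(obj2, obj * (1 + 1e-9))
    obj <- obj2
  }
})

test_that("fit recovers planted low-rank structure to near-zero loss", {
  lr <- planted_low_rank(40, 3, seed = 2)
  A <- to_adjacency(lr)
  fit <- nmf_fit(A, NULL, nmf_config(C = 3, gamma = 0, lam = 0,
                                     restarts = 3, max_iter = 2000,
                                     tol = 1e-12, seed = 1))
  expect_lt(fit$objective, 1e-3 * sum(A^2))
})

test_that("fit is deterministic and more restarts never hurt", {
  A <- to_adjacency(erdos_renyi(25, 0.2, seed = 6))
  cfg1 <- nmf_config(C = 3, restarts = 1, max_iter = 60, seed = 5)
  cfg3 <- nmf_config(C = 3, restarts = 3, max_iter = 60, seed = 5)
  f1a <- nmf_fit(A, NULL, cfg1)
  f1b <- nmf_fit(A, NULL, cfg1)
  expect_identical(f1a, f1b)
  f3 <- nmf_fit(A, NULL, cfg3)
  expect_lte(f3$objective, f1a$objective)
  expect_true(all(diff(f3$objective_trace) <=
                    1e-9 * utils::head(f3$objective_trace, -1)))
})

test_that("sparse mode agrees with dense mode where their losses coincide", {
  # complete training graph: every off-diagonal entry is observed, so the
  # sparse mask carries the full edge support and both modes drive the
  # observed-entry loss down; sparse optimizes exactly that quantity
  A <- to_adjacency(erdos_renyi(6, 1, seed = 1))  # K6
  cfgd <- nmf_config(C = 3, gamma = 0, lam = 0, restarts = 1,
                     max_iter = 200, seed = 3, mode = "dense")
  cfgs <- cfgd; cfgs$mode <- "sparse"
  fd <- nmf_fit(A, NULL, cfgd)
  fs <- nmf_fit(A, NULL, cfgs)
  obs <- function(f) sum((1 - (f$W %*% f$H)[A == 1])^2)
  expect_lt(obs(fs), obs(fd) + 1e-6)

  net <- erdos_renyi(200, 0.05, seed = 8)
  sp <- split_edges(net, 0.1, seed = 1)
  A1 <- sp$train_adjacency
  R <- organization_matrix(A1, "linear")
  cfgd <- nmf_config(C = 5, gamma = 0.1, lam = 2, restarts = 1,
                     max_iter = 150, seed = 2, mode = "dense")
  cfgs <- cfgd; cfgs$mode <- "sparse"
  fd <- nmf_fit(A1, R, cfgd)
  fs <- nmf_fit(A1, R, cfgs)
  obs_loss <- function(f) {
    wh <- (f$W %*% f$H)[A1 == 1]
    q <- (1 + 0.1 * R)[A1 == 1]
    sum(q * (1 - wh)^2)
  }
  # sparse mode optimizes exactly the observed-entry loss, dense nearly so
  expect_lt(obs_loss(fs), obs_loss(fd) * 1.05)
})

test_that("sparse-mode iteration time grows with edge count", {
  times <- sapply(c(0.012, 0.05), function(p) {
    net <- erdos_renyi(300, p, seed = 3)
    A <- to_adjacency(net)
    cfg <- nmf_config(C = 4, gamma = 0, lam = 1, restarts = 1,
                      max_iter = 30, tol = 1e-15, seed = 1, mode = "sparse")
    median(sapply(1:3, function(i) system.time(nmf_fit(A, NULL, cfg))[3]))
  })
  expect_gt(times[2], times[1])
})

test_that("symmetrized scores separate planted blocks on the candidate set", {
  net <- planted_partition(200, 2, 0.3, 0.02, seed = 11)
  block <- attr(net, "block")
  sp <- split_edges(net, 0.1, seed = 1)
  R <- organization_matrix(sp$train_adjacency, "linear")
  fit <- nmf_fit(sp$train_adjacency, R,
                 nmf_config(C = 4, restarts = 2, max_iter = 200, seed = 9))
  sc <- predict_scores(fit, sp)
  expect_equal(nrow(sc), nrow(candidate_pairs(sp)))
  within <- block[sc$i] == block[sc$j]
  expect_gt(mean(sc$score[within]), mean(sc$score[!within]))
  # symmetrization: S is symmetric by construction
  S <- fit$W %*% fit$H
  S <- (S + t(S)) / 2
  expect_equal(S, t(S))
})

test_that("rank selection finds planted spectral structure and caps at max_C", {
  u <- matrix(1, 6, 1)
  expect_equal(select_rank(u %*% t(u)), 1L)
  expect_equal(select_rank(diag(30), max_C = 5L), 5L)
  set.seed(2)
  U <- qr.Q(qr(matrix(rnorm(60 * 3), 60, 3)))
  B <- U %*% t(U)                       # three equal singular values
  noise <- matrix(rnorm(3600, sd = 1e-4), 60)
  expect_equal(select_rank(B + (noise + t(noise)) / 2, max_C = 10L), 3L)
})
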