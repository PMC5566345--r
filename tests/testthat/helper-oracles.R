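# Independent oracles used across the suite.  Each is deliberately written
# the slow, obvious way (scalar loops, linear solves, exhaustive
# enumeration) so it shares no code path with the implementation it checks.

# Build an lp_split directly: training graph = `train` edge pairs, held-out
# test edges = `test` pairs.  Lets tests pin exact worked examples (e.g.
# "P3 as training, score pair (1,3)") without relying on a random draw.
make_split <- function(n, train, test, labels = as.character(seq_len(n)),
                       seed = 0L) {
  train <- matrix(as.integer(train), ncol = 2L, byrow = TRUE)
  test <- matrix(as.integer(test), ncol = 2L, byrow = TRUE)
  A1 <- matrix(0, n, n)
  A1[train] <- 1
  A1[train[, c(2L, 1L)]] <- 1
  structure(
    list(train_adjacency = A1, train_edges = train, test_edges = test,
         n = n, m = nrow(train) + nrow(test), L = nrow(test),
         seed = seed, labels = labels),
    class = "lp_split")
}

# Classical Lee-Seung multiplicative update (quadratic loss, no weights, no
# regularization), scalar loops; W updated first, then H with the new W.
ref_leeseung_update <- function(A, W, H) {
  n1 <- nrow(A); n2 <- ncol(A); C <- ncol(W)
  Wn <- W
  for (i in seq_len(n1)) for (z in seq_len(C)) {
    num <- 0; den <- 0
    for (j in seq_len(n2)) {
      whij <- sum(W[i, ] * H[, j])
      num <- num + A[i, j] * H[z, j]
      den <- den + whij * H[z, j]
    }
    Wn[i, z] <- W[i, z] * num / max(den, 1e-12)
  }
  Hn <- H
  for (z in seq_len(C)) for (j in seq_len(n2)) {
    num <- 0; den <- 0
    for (i in seq_len(n1)) {
      whij <- sum(Wn[i, ] * H[, j])
      num <- num + Wn[i, z] * A[i, j]
      den <- den + Wn[i, z] * whij
    }
    Hn[z, j] <- H[z, j] * num / max(den, 1e-12)
  }
  list(W = Wn, H = Hn)
}

# Fused objective by scalar loops.
ref_objective <- function(A, R, W, H, gamma, lam) {
  n <- nrow(A)
  o <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    q <- if (is.null(R)) 1 else 1 + gamma * R[i, j]
    o <- o + q * (A[i, j] - sum(W[i, ] * H[, j]))^2
  }
  o + lam * (sum(W^2) + sum(H^2))
}

# Two-pass sample covariance of the columns of A.
ref_covariance <- function(A) {
  n <- ncol(A)
  mu <- rowMeans(A)
  S <- matrix(0, nrow(A), nrow(A))
  for (i in seq_len(n)) S <- S + tcrossprod(A[, i] - mu)
  S / (n - 1)
}

# Exact AUC by exhaustive double loop.
ref_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# Average-commute-time similarity via random-walk hitting times: solve the
# first-step equations for the expected hitting time H(x -> y), form the
# commute time C = H(x,y) + H(y,x), and use s = 2m / C (commute time equals
# 2m times effective resistance).  Connected graphs only.
ref_act <- function(A, x, y) {
  n <- nrow(A)
  deg <- rowSums(A)
  P <- A / deg
  hitting <- function(target, from) {
    keep <- setdiff(seq_len(n), target)
    M <- diag(length(keep)) - P[keep, keep, drop = FALSE]
    h <- solve(M, rep(1, length(keep)))
    h[match(from, keep)]
  }
  ct <- hitting(y, x) + hitting(x, y)
  2 * (sum(A) / 2) / ct
}

# RNG isolation for test-local draws.
with_seed_for_test <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Brute-force candidate enumeration: pairs i < j absent from A1.
ref_candidates <- function(A1) {
  n <- nrow(A1)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (A1[i, j] == 0) out <- rbind(out, c(i, j))
  out
}
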