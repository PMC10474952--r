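# Independent reference implementations used only as test oracles. These are
# written as naive element-by-element loops, deliberately sharing no code
# with the package.

# pairwise Chebyshev distances by double loop
oracle_chebyshev_matrix <- function(F) {
  n <- nrow(F)
  D <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    best <- 0
    for (c in seq_len(ncol(F))) {
      d <- abs(F[a, c] - F[b, c])
      if (d > best) best <- d
    }
    D[a, b] <- best
  }
  D
}

# dense-loop similarity network fusion
oracle_snf <- function(Ws, K, T) {
  n <- nrow(Ws[[1]]); V <- length(Ws)
  normalize_full <- function(W) {
    P <- matrix(0, n, n)
    for (i in seq_len(n)) {
      rs <- 0
      for (j in seq_len(n)) if (j != i) rs <- rs + W[i, j]
      for (j in seq_len(n)) {
        P[i, j] <- if (i == j) 0.5 else if (rs > 0) W[i, j] / (2 * rs) else 0
      }
    }
    P
  }
  knn_sparse <- function(W) {
    S <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(-W[i, ], seq_len(n))[seq_len(K)]
      tot <- 0
      for (j in nb) tot <- tot + W[i, j]
      for (j in nb) S[i, j] <- W[i, j] / max(tot, 1e-12)
    }
    S
  }
  P <- lapply(Ws, normalize_full)
  S <- lapply(Ws, knn_sparse)
  if (T > 0) for (t in seq_len(T)) {
    Pnew <- vector("list", V)
    for (v in seq_len(V)) {
      Pbar <- matrix(0, n, n)
      for (u in seq_len(V)) if (u != v) Pbar <- Pbar + P[[u]]
      Pbar <- Pbar / (V - 1)
      Q <- S[[v]] %*% Pbar %*% t(S[[v]])
      Q <- (Q + t(Q)) / 2
      Pnew[[v]] <- normalize_full(Q)
    }
    P <- Pnew
  }
  out <- matrix(0, n, n)
  for (v in seq_len(V)) out <- out + P[[v]]
  out <- out / V
  (out + t(out)) / 2
}

# textbook regression metrics
oracle_metrics <- function(pred, truth) {
  n <- length(pred)
  rmse <- sqrt(sum((pred - truth)^2) / n)
  mae <- sum(abs(pred - truth)) / n
  mp <- sum(pred) / n; mt <- sum(truth) / n
  r <- sum((pred - mp) * (truth - mt)) /
    sqrt(sum((pred - mp)^2) * sum((truth - mt)^2))
  list(rmse = rmse, mae = mae, r = r)
}

# random symmetric [0,1] similarity matrix with unit diagonal
random_similarity <- function(n, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  A
}
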