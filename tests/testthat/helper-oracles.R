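# Independent oracles used to freeze expected values. Each is a literal,
# unoptimized implementation kept deliberately separate from the package's
# code paths.

# Alternating non-negative least squares to convergence, multi-restart.
anls_oracle <- function(X, k, n_restarts = 10, max_sweeps = 500, tol = 1e-10,
                        seed = 1) {
  set.seed(seed)
  best <- Inf
  for (r in seq_len(n_restarts)) {
    A <- matrix(runif(nrow(X) * k, 0.1, 1), nrow(X), k)
    P <- matrix(runif(k * ncol(X), 0.1, 1), k, ncol(X))
    err_prev <- Inf
    for (s in seq_len(max_sweeps)) {
      for (i in seq_len(nrow(X))) {
        A[i, ] <- pracma::lsqnonneg(t(P), X[i, ])$x
      }
      for (j in seq_len(ncol(X))) {
        P[, j] <- pracma::lsqnonneg(A, X[, j])$x
      }
      err <- norm(X - A %*% P, "F")
      if (err_prev - err < tol * max(err_prev, 1e-12)) break
      err_prev <- err
    }
    best <- min(best, err)
  }
  best
}

# Literal weighted running-sum enrichment statistic over the whole list.
es_oracle <- function(symbols, weights, set, exponent = 1) {
  N <- length(symbols)
  hit <- symbols %in% set
  nh <- sum(hit)
  wsum <- sum(weights[hit]^exponent)
  running <- 0
  peak <- 0
  for (i in seq_len(N)) {
    running <- running + if (hit[i]) {
      if (wsum > 0) weights[i]^exponent / wsum else 1 / nh
    } else {
      -1 / (N - nh)
    }
    peak <- max(peak, running)
  }
  peak
}

# Closed-form pooled-variance two-sample t-test.
pooled_t_oracle <- function(x, y) {
  na <- length(x); nb <- length(y)
  df <- na + nb - 2
  sp2 <- ((na - 1) * var(x) + (nb - 1) * var(y)) / df
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Best correlation between recovered and planted sample-weight rows over all
# pattern permutations (exhaustive for small k, greedy matching otherwise).
best_match_correlation <- function(P_hat, P_true) {
  k <- nrow(P_true)
  cors <- suppressWarnings(cor(t(P_hat), t(P_true)))
  cors[!is.finite(cors)] <- -1
  if (k <= 6) {
    perms <- pracma::perms(seq_len(k))
    best <- -Inf
    for (i in seq_len(nrow(perms))) {
      m <- mean(cors[cbind(perms[i, ], seq_len(k))])
      if (m > best) best <- m
    }
    best
  } else {
    used <- integer(0)
    vals <- numeric(k)
    for (j in order(-apply(cors, 2, max))) {
      cand <- order(-cors[, j])
      cand <- cand[!cand %in% used][1]
      used <- c(used, cand)
      vals[j] <- cors[cand, j]
    }
    mean(vals)
  }
}
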