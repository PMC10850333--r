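# Independent oracles used across the suite. Each is a deliberately naive
# from-scratch implementation (loops, explicit normal equations, projected
# gradient) kept free of the package's own code paths.

# Exhaustive greedy SPXY: recomputes every pairwise joint distance at every
# step with explicit loops.
oracle_spxy <- function(X, y, n_train) {
  n <- nrow(X)
  dx <- matrix(0, n, n); dy <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dx[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    dy[i, j] <- abs(y[i] - y[j])
  }
  D <- dx / max(dx)
  if (max(dy) > 0) D <- D + dy / max(dy)
  bi <- c(NA, NA); bv <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (D[i, j] > bv) { bv <- D[i, j]; bi <- c(i, j) }
  sel <- if (n_train == 1) bi[1] else bi
  while (length(sel) < n_train) {
    cand <- NA; cv <- -Inf
    for (r in setdiff(seq_len(n), sel)) {
      mv <- Inf
      for (s in sel) mv <- min(mv, D[r, s])
      if (mv > cv) { cv <- mv; cand <- r }
    }
    sel <- c(sel, cand)
  }
  sort(sel)
}

# Brute-force SPA chain: explicit Gram-Schmidt basis, exhaustive residual
# norm comparison at every step.
oracle_spa_chain <- function(X, start, k) {
  chain <- start
  basis <- list()
  for (step in seq_len(k - 1)) {
    v <- X[, chain[length(chain)]]
    for (b in basis) v <- v - sum(v * b) * b
    basis[[length(basis) + 1]] <- v / sqrt(sum(v^2))
    best <- NA; bv <- -1
    for (j in seq_len(ncol(X))) {
      if (j %in% chain) next
      r <- X[, j]
      for (b in basis) r <- r - sum(r * b) * b
      nr <- sum(r^2)
      if (nr > bv) { bv <- nr; best <- j }
    }
    chain <- c(chain, best)
  }
  chain
}

# Per-window least-squares smoothing oracle via explicit normal equations.
oracle_sg_row <- function(x, window, polyorder) {
  p <- length(x); h <- (window - 1) / 2
  out <- numeric(p)
  for (i in seq_len(p)) {
    start <- min(max(i - h, 1), p - window + 1)
    pos <- start:(start + window - 1)
    A <- outer(pos - i, 0:polyorder, `^`)
    beta <- solve(t(A) %*% A) %*% (t(A) %*% x[pos])
    out[i] <- beta[1]
  }
  out
}

# Dual objective of epsilon-SVR for a given signed dual vector.
svr_dual_objective <- function(K, y, s, epsilon) {
  n <- length(y)
  beta <- s[seq_len(n)] + s[n + seq_len(n)]
  0.5 * drop(beta %*% K %*% beta) +
    epsilon * (sum(s[seq_len(n)]) - sum(s[n + seq_len(n)])) - sum(y * beta)
}

# Accelerated projected-gradient (FISTA) solver for the epsilon-SVR dual
# QP (oracle for tiny problems). Projection onto {sum(s) = 0,
# lb <= s <= ub} by bisection on the shift multiplier.
oracle_svr_dual <- function(K, y, C, epsilon, iters = 5000) {
  n <- length(y)
  q <- c(epsilon - y, -epsilon - y)
  lb <- c(rep(0, n), rep(-C, n))
  ub <- c(rep(C, n), rep(0, n))
  Kt <- rbind(cbind(K, K), cbind(K, K))
  L <- 2 * max(eigen(K, symmetric = TRUE, only.values = TRUE)$values) + 1e-9
  proj <- function(v) {
    f <- function(mu) sum(pmin(pmax(v - mu, lb), ub))
    lo <- min(v - ub) - 1; hi <- max(v - lb) + 1
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    pmin(pmax(v - (lo + hi) / 2, lb), ub)
  }
  s <- proj(numeric(2 * n))
  z <- s
  tk <- 1
  best <- s
  best_obj <- svr_dual_objective(K, y, s, epsilon)
  for (it in seq_len(iters)) {
    g <- drop(Kt %*% z) + q
    s_new <- proj(z - g / L)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- s_new + ((tk - 1) / t_new) * (s_new - s)
    s <- s_new
    tk <- t_new
    if (it %% 100 == 0) {
      ob <- svr_dual_objective(K, y, s, epsilon)
      if (ob < best_obj) { best_obj <- ob; best <- s }
    }
  }
  ob <- svr_dual_objective(K, y, s, epsilon)
  if (ob < best_obj) { best_obj <- ob; best <- s }
  list(s = best, objective = best_obj)
}

# Naive direct 1-D convolution network forward pass (per position, per
# sample), independent of the package's im2col path.
oracle_net_forward <- function(net, x) {
  spec <- net$spec
  pr <- net$params
  lam <- 1.0507009873554804934193349852946
  alp <- 1.6732632423543772848170429916717
  act <- function(z) switch(spec$activation,
                            selu = lam * ifelse(z > 0, z, alp * (exp(z) - 1)),
                            relu = pmax(z, 0),
                            sigmoid = 1 / (1 + exp(-z)))
  conv <- function(A, W, b) {
    C_in <- nrow(A); L <- ncol(A); k <- ncol(W) / C_in
    h <- (k - 1) / 2
    Ap <- cbind(matrix(0, C_in, h), A, matrix(0, C_in, h))
    Z <- matrix(0, nrow(W), L)
    for (t in seq_len(L)) Z[, t] <- W %*% as.vector(Ap[, t:(t + k - 1)]) + b
    Z
  }
  A1 <- act(conv(matrix(x, 1), pr$W1, pr$b1))
  A2 <- act(conv(A1, pr$W2, pr$b2))
  A3 <- act(conv(A2, pr$W3, pr$b3))
  Lp <- ncol(A3) %/% spec$pool_window
  P <- matrix(0, nrow(A3), Lp)
  for (t in seq_len(Lp))
    P[, t] <- rowMeans(A3[, (spec$pool_window * (t - 1) + 1):
                              (spec$pool_window * t), drop = FALSE])
  drop(pr$W4 %*% as.vector(P)) + pr$b4
}

# 5-fold round-robin CV RMSE of ordinary multiple linear regression,
# written independently of the package helper.
oracle_mlr_cv_rmse <- function(X, y, cols, folds = 5) {
  n <- length(y)
  fid <- rep_len(seq_len(folds), n)
  sse <- 0
  for (f in seq_len(folds)) {
    tr <- fid != f
    A <- cbind(1, X[tr, cols, drop = FALSE])
    cf <- qr.coef(qr(A), y[tr])
    cf[is.na(cf)] <- 0
    pred <- drop(cbind(1, X[!tr, cols, drop = FALSE]) %*% cf)
    sse <- sse + sum((y[!tr] - pred)^2)
  }
  sqrt(sse / n)
}

# Small planted-truth regression dataset.
make_planted <- function(n, p, cols, coefs, noise_sd, seed) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X[, cols, drop = FALSE] %*% coefs) + rnorm(n, 0, noise_sd)
    list(X = X, y = y)
  })
}
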