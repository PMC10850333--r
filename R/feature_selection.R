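#' Successive projection chain
#'
#' Starting from column `start`, repeatedly projects every remaining column
#' onto the orthogonal complement of the span of the already-chosen columns
#' and appends the column with the largest residual norm. This is the inner
#' primitive of SPA: it builds maximally non-collinear wavelength chains.
#' Columns are expected to be mean-centered by the caller (as [spa_select()]
#' does); the function does not center.
#'
#' @param X numeric matrix with mean-centered columns.
#' @param start index of the first column of the chain.
#' @param k chain length, `k <= min(p, n - 1)`.
#' @return Integer vector of `k` column indices, beginning with `start`.
#' @export
successive_projection <- function(X, start, k) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  start <- as.integer(start); k <- as.integer(k)
  if (start < 1L || start > p) stop("start column out of range")
  if (k < 1L || k > min(p, n - 1L))
    stop(sprintf("chain length k must lie in [1, %d]", min(p, n - 1L)))
  R <- X
  if (sum(R[, start]^2) < 1e-24)
    stop(sprintf("zero-variance start column %d", start))
  chain <- integer(k)
  chain[1L] <- start
  for (step in seq_len(k - 1L)) {
    q <- R[, chain[step]]
    q <- q / sqrt(sum(q^2))
    R <- R - q %o% drop(crossprod(R, q))
    R[, chain[seq_len(step)]] <- 0
    norms <- colSums(R^2)
    norms[chain[seq_len(step)]] <- -1
    chain[step + 1L] <- which.max(norms)
  }
  chain
}

# Cross-validated RMSE of multiple linear regression on a fixed column
# subset. Rank-deficient subsets are handled by lm.fit's pivoting: aliased
# coefficients are set to zero (a least-squares pseudo-solution), never an
# error.
mlr_cv_rmse <- function(X, y, cols, fold_id) {
  sse <- 0
  for (f in unique(fold_id)) {
    tr <- fold_id != f
    A <- cbind(1, X[tr, cols, drop = FALSE])
    fit <- stats::lm.fit(A, y[tr])
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    pred <- drop(cbind(1, X[!tr, cols, drop = FALSE]) %*% cf)
    sse <- sse + sum((y[!tr] - pred)^2)
  }
  sqrt(sse / length(y))
}

#' SPA wavelength selection
#'
#' Evaluates every (start column, chain length m) candidate produced by
#' [successive_projection()] for `m` in `[min_vars, max_vars]`, scoring each
#' subset by the k-fold cross-validated RMSE of a multiple linear
#' regression on the training set, and returns the subset with minimum
#' CV-RMSE. Deterministic: folds are assigned round-robin and ties are
#' broken toward the smaller subset, then the lexicographically smaller
#' sorted index tuple.
#'
#' @param X_train training reflectance matrix (pretreated).
#' @param y_train training target vector.
#' @param min_vars,max_vars candidate subset size range; `max_vars` defaults
#'   to `min(30, p, n_train - 2)`.
#' @param cv_folds number of cross-validation folds.
#' @return A [selection_result()] with method `"spa"`; `scores` is the
#'   CV-RMSE-versus-m path of the winning start column (named by m).
#' @export
spa_select <- function(X_train, y_train, min_vars = 2L, max_vars = NULL,
                       cv_folds = 5L) {
  X <- as.matrix(X_train)
  n <- nrow(X); p <- ncol(X)
  if (is.null(max_vars)) max_vars <- min(30L, p, n - 2L)
  min_vars <- as.integer(min_vars); max_vars <- as.integer(max_vars)
  if (min_vars < 1L || min_vars > max_vars)
    stop("need 1 <= min_vars <= max_vars")
  if (max_vars > min(p, n - 2L))
    stop(sprintf("max_vars must be <= min(p, n_train - 2) = %d",
                 min(p, n - 2L)))
  Xc <- sweep(X, 2L, colMeans(X))
  fold_id <- rep_len(seq_len(cv_folds), n)
  ms <- min_vars:max_vars

  best <- list(rmse = Inf, subset = NULL, path = NULL)
  tol <- 1e-12
  for (start in seq_len(p)) {
    if (sum(Xc[, start]^2) < 1e-24) next
    chain <- successive_projection(Xc, start, max_vars)
    path <- vapply(ms, function(m)
      mlr_cv_rmse(X, y_train, chain[seq_len(m)], fold_id), numeric(1L))
    for (i in seq_along(ms)) {
      cand <- chain[seq_len(ms[i])]
      r <- path[i]
      better <- r < best$rmse - tol ||
        (abs(r - best$rmse) <= tol && !is.null(best$subset) &&
           (length(cand) < length(best$subset) ||
              (length(cand) == length(best$subset) &&
                 lex_less(sort(cand), sort(best$subset)))))
      if (better) {
        best <- list(rmse = r, subset = cand,
                     path = stats::setNames(path, ms))
      }
    }
  }
  if (is.null(best$subset)) stop("no usable start column (all zero variance)")
  selection_result(best$subset, scores = best$path, method = "spa", p = p)
}

lex_less <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# Cross-validated RMSE of the inner PLS model used by random frog.
pls_cv_rmse <- function(X, y, cols, fold_id, ncomp, center) {
  sse <- 0
  for (f in unique(fold_id)) {
    tr <- fold_id != f
    ntr <- sum(tr)
    fit <- pls1_core(X[tr, cols, drop = FALSE], y[tr],
                     min(ncomp, length(cols), ntr - 1L), center = center)
    pred <- drop(sweep(X[!tr, cols, drop = FALSE], 2L, fit$x_mean) %*%
                   fit$beta) + fit$y_mean
    sse <- sse + sum((y[!tr] - pred)^2)
  }
  sqrt(sse / length(y))
}

#' Random frog wavelength selection
#'
#' Iterative stochastic subset search. Each iteration proposes a candidate
#' dimension `Q* = max(1, min(p, round(|N(Q, theta * Q)|)))`; the candidate
#' subset keeps the top `Q*` variables (by absolute inner-PLS regression
#' coefficient) when shrinking, or adds the top-ranked remaining variables
#' when growing. The candidate replaces the current subset if its inner
#' cross-validated RMSE improves, or with probability
#' `eta * RMSE_old / RMSE_new` otherwise. Each variable's selection
#' probability is its inclusion frequency across the `n_iter` accepted
#' subsets. The defaults follow the study configuration: 1000 iterations,
#' initial subset of 5 variables, mean-centering ("center") inside the
#' inner PLS model; `theta` and `eta` follow the original random-frog
#' literature.
#'
#' @param X_train training reflectance matrix (pretreated).
#' @param y_train training target vector.
#' @param n_iter number of iterations.
#' @param q_init initial subset size (`1 <= q_init <= p`).
#' @param theta proposal spread factor for `Q*`.
#' @param eta acceptance damping for non-improving candidates.
#' @param inner_components maximum components of the inner PLS model.
#' @param center mean-center X and y inside the inner model.
#' @param cv_folds folds for the inner cross-validation.
#' @param seed RNG seed (proposals, acceptance draws, fold shuffle).
#' @param final_k `"auto"` (choose the probability-ranked prefix with
#'   minimum inner CV-RMSE) or a fixed subset size.
#' @return A [selection_result()] with method `"frog"`; `scores` is the
#'   length-p selection-probability vector.
#' @export
random_frog_select <- function(X_train, y_train, n_iter = 1000L,
                               q_init = 5L, theta = 0.3, eta = 0.1,
                               inner_components = 5L, center = TRUE,
                               cv_folds = 5L, seed = 1L, final_k = "auto") {
  X <- as.matrix(X_train)
  n <- nrow(X); p <- ncol(X)
  n_iter <- as.integer(n_iter); q_init <- as.integer(q_init)
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (q_init < 1L || q_init > p)
    stop(sprintf("q_init must lie in [1, %d]", p))
  if (n < cv_folds + 1L) stop("too few samples for the inner CV")

  withr::with_seed(seed, {
    fold_id <- sample(rep_len(seq_len(cv_folds), n))
    cvr <- function(cols) pls_cv_rmse(X, y_train, cols, fold_id,
                                      inner_components, center)
    # static grow-step ranking: |PLS coefficient| from one fit on all p
    full_fit <- pls1_core(X, y_train, min(inner_components, p, n - 1L),
                          center = center)
    grow_rank <- order(-abs(full_fit$beta), seq_len(p))

    V0 <- sort(sample.int(p, q_init))
    rmse0 <- cvr(V0)
    if (!is.finite(rmse0)) stop("inner model error is non-finite")
    counts <- numeric(p)
    for (it in seq_len(n_iter)) {
      Q0 <- length(V0)
      Qs <- max(1L, min(p, as.integer(round(abs(stats::rnorm(1L, Q0,
                                                             theta * Q0))))))
      if (Qs > Q0) {
        add <- setdiff(grow_rank, V0)[seq_len(Qs - Q0)]
        Vs <- sort(c(V0, add))
      } else if (Qs < Q0) {
        fit0 <- pls1_core(X[, V0, drop = FALSE], y_train,
                          min(inner_components, Q0, n - 1L), center = center)
        keep <- order(-abs(fit0$beta), seq_len(Q0))[seq_len(Qs)]
        Vs <- sort(V0[keep])
      } else {
        Vs <- V0
      }
      if (!identical(Vs, V0)) {
        rmse_s <- cvr(Vs)
        if (!is.finite(rmse_s)) stop("inner model error is non-finite")
        accept <- rmse_s < rmse0 ||
          stats::runif(1L) < eta * (rmse0 / rmse_s)
        if (accept) {
          V0 <- Vs
          rmse0 <- rmse_s
        }
      }
      counts[V0] <- counts[V0] + 1
    }
    probs <- counts / n_iter

    ord <- order(-probs, seq_len(p))
    if (identical(final_k, "auto")) {
      kmax <- min(p, n - 2L)
      krmse <- vapply(seq_len(kmax), function(k) cvr(sort(ord[seq_len(k)])),
                      numeric(1L))
      k <- which.min(krmse)
    } else {
      k <- as.integer(final_k)
      if (k < 1L || k > p) stop("final_k out of range")
    }
    selection_result(ord[seq_len(k)], scores = probs, method = "frog", p = p)
  })
}
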