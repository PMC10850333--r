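# NIPALS PLS1. Returns the regression vector on (optionally centered)
# inputs; components stop early when the residual covariance vanishes.
pls1_core <- function(X, y, ncomp, center = TRUE, strict = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L) stop("n_components must be >= 1")
  xm <- if (center) colMeans(X) else numeric(p)
  ym <- if (center) mean(y) else 0
  E <- sweep(X, 2L, xm)
  f <- y - ym
  A <- min(ncomp, p, n - if (center) 1L else 0L)
  W <- matrix(0, p, A); P <- matrix(0, p, A); q <- numeric(A)
  used <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    tt <- drop(E %*% w)
    t2 <- sum(tt^2)
    if (t2 < 1e-24) break
    pl <- drop(crossprod(E, tt)) / t2
    qa <- sum(f * tt) / t2
    E <- E - tt %o% pl
    f <- f - qa * tt
    W[, a] <- w; P[, a] <- pl; q[a] <- qa
    used <- a
  }
  if (strict && used < ncomp)
    stop(sprintf("n_components = %d exceeds the effective rank (%d usable)",
                 ncomp, used))
  beta <- if (used > 0L) {
    Wu <- W[, seq_len(used), drop = FALSE]
    Pu <- P[, seq_len(used), drop = FALSE]
    drop(Wu %*% solve(crossprod(Pu, Wu), q[seq_len(used)]))
  } else numeric(p)
  list(beta = beta, x_mean = xm, y_mean = ym, ncomp = used)
}

new_feature_guard <- function(X) {
  list(p = ncol(X), names = colnames(X))
}

check_features <- function(guard, X) {
  if (ncol(X) != guard$p)
    stop(sprintf("feature count mismatch: model expects %d columns, got %d",
                 guard$p, ncol(X)))
  if (!is.null(guard$names) && !is.null(colnames(X)) &&
      !identical(colnames(X), guard$names))
    stop("feature columns do not match the training columns (order matters)")
  invisible(TRUE)
}

#' Partial least squares regression (PLS1)
#'
#' NIPALS PLS1 on mean-centered data. The stored regression vector alone
#' reproduces predictions: `yhat = (X - x_mean) beta + y_mean`. The default
#' of 4 components follows the study configuration.
#'
#' @param X training matrix (rows = samples).
#' @param y training target vector.
#' @param n_components number of latent components; errors if it exceeds
#'   `min(n - 1, p)`, the rank cap of the centered training matrix.
#'   Components whose residual covariance vanishes earlier (exactly
#'   collinear data) stop the extraction silently, as standard PLS
#'   implementations do; `n_components` in the fitted object reports the
#'   number actually used.
#' @return Object of class `plsr_model`.
#' @export
fit_plsr <- function(X, y, n_components = 4L) {
  X <- as.matrix(X)
  if (anyNA(X) || !all(is.finite(X)) || anyNA(y) || !all(is.finite(y)))
    stop("X and y must be finite")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (n_components > min(nrow(X) - 1L, ncol(X)))
    stop(sprintf("n_components = %d exceeds the rank cap min(n - 1, p) = %d",
                 n_components, min(nrow(X) - 1L, ncol(X))))
  fit <- pls1_core(X, y, n_components, center = TRUE)
  structure(list(n_components = fit$ncomp, beta = fit$beta,
                 x_mean = fit$x_mean, y_mean = fit$y_mean,
                 guard = new_feature_guard(X),
                 fitted = drop(sweep(X, 2L, fit$x_mean) %*% fit$beta) +
                   fit$y_mean),
            class = "plsr_model")
}

#' @export
predict.plsr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  check_features(object$guard, newdata)
  drop(sweep(newdata, 2L, object$x_mean) %*% object$beta) + object$y_mean
}

rbf_kernel <- function(A, B, gamma) {
  # exp(-gamma * ||a - b||^2), rows of A x rows of B
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

standardize_fit <- function(X) {
  m <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(mean = m, sd = s)
}

standardize_apply <- function(X, sc) {
  sweep(sweep(X, 2L, sc$mean), 2L, sc$sd, `/`)
}

seeded_folds <- function(n, k, seed) {
  withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Least-squares support vector machine regression
#'
#' Solves the LSSVM KKT linear system
#' `[[0, 1'], [1, Omega + I/gamma]] [b; alpha] = [0; y]` with the RBF
#' kernel `Omega_ij = exp(-||x_i - x_j||^2 / (2 sigma^2))`; prediction is
#' `f(x) = sum_i alpha_i k(x_i, x) + b`. Features are standardized
#' internally so the kernel width is comparable across pretreatments. When
#' `gamma` and/or `sigma2` are vectors, the pair is chosen by seeded k-fold
#' cross-validated RMSE over the grid (ties: smallest `gamma`, then
#' smallest `sigma2`).
#'
#' @param X training matrix.
#' @param y training target vector.
#' @param gamma regularization parameter(s); default ladder `10^(-3:3)`.
#' @param sigma2 squared RBF width(s); default ladder `10^(-3:3)`.
#' @param cv_folds,seed cross-validation controls for the grid search.
#' @return Object of class `lssvm_model`.
#' @export
fit_lssvm <- function(X, y, gamma = 10^(-3:3), sigma2 = 10^(-3:3),
                      cv_folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (any(gamma <= 0) || any(sigma2 <= 0))
    stop("gamma and sigma2 must be positive")
  if (length(gamma) > 1L || length(sigma2) > 1L) {
    fold_id <- seeded_folds(nrow(X), cv_folds, seed)
    best <- NULL
    for (g in sort(gamma)) for (s2 in sort(sigma2)) {
      sse <- 0
      ok <- TRUE
      for (f in seq_len(cv_folds)) {
        tr <- fold_id != f
        fit <- try(fit_lssvm(X[tr, , drop = FALSE], y[tr], g, s2),
                   silent = TRUE)
        if (inherits(fit, "try-error")) { ok <- FALSE; break }
        sse <- sse + sum((y[!tr] - predict(fit, X[!tr, , drop = FALSE]))^2)
      }
      if (!ok) next
      r <- sqrt(sse / nrow(X))
      if (is.null(best) || r < best$rmse - 1e-12)
        best <- list(rmse = r, gamma = g, sigma2 = s2)
    }
    if (is.null(best)) stop("degenerate grid: no (gamma, sigma2) pair fit")
    out <- fit_lssvm(X, y, best$gamma, best$sigma2)
    out$cv_rmse <- best$rmse
    return(out)
  }

  sc <- standardize_fit(X)
  Xs <- standardize_apply(X, sc)
  n <- nrow(Xs)
  K <- rbf_kernel(Xs, Xs, 1 / (2 * sigma2))
  M <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / gamma))
  sol <- try(solve(M, c(0, y)), silent = TRUE)
  if (inherits(sol, "try-error"))
    stop("singular LSSVM system; try a smaller gamma (larger 1/gamma ridge)")
  structure(list(alpha = sol[-1L], b = sol[1L], gamma = gamma,
                 sigma2 = sigma2, X_train = Xs, scaling = sc,
                 guard = new_feature_guard(X),
                 fitted = drop(K %*% sol[-1L]) + sol[1L]),
            class = "lssvm_model")
}

#' @export
predict.lssvm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  check_features(object$guard, newdata)
  Xs <- standardize_apply(newdata, object$scaling)
  K <- rbf_kernel(Xs, object$X_train, 1 / (2 * object$sigma2))
  drop(K %*% object$alpha) + object$b
}

# SMO solver for the epsilon-SVR dual, written in the signed-dual
# formulation s in R^{2n}: s[1:n] = alpha (in [0, C]), s[n+1:2n] = -alpha*
# (in [-C, 0]), beta = s[1:n] + s[n+1:2n], subject to sum(s) = 0.
# Objective: 0.5 beta' K beta + eps * (sum alpha + sum alpha*) - y' beta.
# Most-violating-pair selection; returns beta, bias, final objective.
svr_smo <- function(K, y, C, epsilon, tol = 1e-8, max_iter = 200000L) {
  n <- length(y)
  s <- numeric(2L * n)
  ub <- c(rep(C, n), rep(0, n))
  lb <- c(rep(0, n), rep(-C, n))
  Fv <- numeric(n)                 # K beta
  smp <- c(seq_len(n), seq_len(n)) # dual index -> sample index
  iter <- 0L
  repeat {
    g <- c(Fv + epsilon - y, Fv - epsilon - y)  # gradient in s-space
    ng <- -g
    up <- s < ub - 1e-15
    lo <- s > lb + 1e-15
    if (!any(up) || !any(lo)) break
    m_val <- max(ng[up]); i <- which(up)[which.max(ng[up])]
    M_val <- min(ng[lo]); j <- which(lo)[which.min(ng[lo])]
    if (m_val - M_val <= tol || iter >= max_iter) break
    a <- smp[i]; b2 <- smp[j]
    eta <- K[a, a] + K[b2, b2] - 2 * K[a, b2]
    delta <- if (eta > 1e-12) (m_val - M_val) / eta else Inf
    delta <- min(delta, ub[i] - s[i], s[j] - lb[j])
    s[i] <- s[i] + delta
    s[j] <- s[j] - delta
    Fv <- Fv + delta * (K[, a] - K[, b2])
    iter <- iter + 1L
  }
  g <- c(Fv + epsilon - y, Fv - epsilon - y)
  ng <- -g
  up <- s < ub - 1e-15; lo <- s > lb + 1e-15
  bias <- (if (any(up)) max(ng[up]) else 0) / 2 +
    (if (any(lo)) min(ng[lo]) else 0) / 2
  beta <- s[seq_len(n)] + s[n + seq_len(n)]
  obj <- 0.5 * sum(beta * Fv) +
    epsilon * (sum(s[seq_len(n)]) - sum(s[n + seq_len(n)])) - sum(y * beta)
  list(beta = beta, b = bias, objective = obj, iterations = iter)
}

#' Epsilon-insensitive support vector regression
#'
#' Standard epsilon-SVR with RBF kernel `k(u, v) = exp(-gamma ||u - v||^2)`,
#' solved in the dual by sequential minimal optimization with
#' most-violating-pair working-set selection. Features are standardized
#' internally. When `C` and/or `gamma` are vectors, the pair is chosen by
#' seeded k-fold cross-validated RMSE (ties: smallest `C`, then smallest
#' `gamma`).
#'
#' @param X training matrix.
#' @param y training target vector.
#' @param C regularization parameter(s); default ladder `10^(-3:3)`.
#' @param gamma RBF width parameter(s); default ladder `10^(-3:3)`.
#' @param epsilon insensitivity-tube half-width.
#' @param cv_folds,seed cross-validation controls for the grid search.
#' @param tol,max_iter SMO convergence controls.
#' @return Object of class `svr_model`; `coefficients` holds the dual
#'   expansion weights (bounded by `C` in absolute value), `b` the bias.
#' @export
fit_svr <- function(X, y, C = 10^(-3:3), gamma = 10^(-3:3), epsilon = 0.01,
                    cv_folds = 5L, seed = 1L, tol = 1e-8,
                    max_iter = 200000L) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (any(C <= 0) || any(gamma <= 0) || epsilon < 0)
    stop("need C > 0, gamma > 0, epsilon >= 0")
  if (length(C) > 1L || length(gamma) > 1L) {
    fold_id <- seeded_folds(nrow(X), cv_folds, seed)
    best <- NULL
    for (cc in sort(C)) for (g in sort(gamma)) {
      sse <- 0
      for (f in seq_len(cv_folds)) {
        tr <- fold_id != f
        fit <- fit_svr(X[tr, , drop = FALSE], y[tr], cc, g, epsilon,
                       tol = tol, max_iter = max_iter)
        sse <- sse + sum((y[!tr] - predict(fit, X[!tr, , drop = FALSE]))^2)
      }
      r <- sqrt(sse / nrow(X))
      if (is.null(best) || r < best$rmse - 1e-12)
        best <- list(rmse = r, C = cc, gamma = g)
    }
    out <- fit_svr(X, y, best$C, best$gamma, epsilon,
                   tol = tol, max_iter = max_iter)
    out$cv_rmse <- best$rmse
    return(out)
  }

  sc <- standardize_fit(X)
  Xs <- standardize_apply(X, sc)
  K <- rbf_kernel(Xs, Xs, gamma)
  if (anyNA(K) || !all(is.finite(K))) stop("non-finite kernel values")
  sol <- svr_smo(K, y, C, epsilon, tol, max_iter)
  structure(list(coefficients = sol$beta, b = sol$b, C = C, gamma = gamma,
                 epsilon = epsilon, X_train = Xs, scaling = sc,
                 objective = sol$objective, guard = new_feature_guard(X),
                 fitted = drop(K %*% sol$beta) + sol$b),
            class = "svr_model")
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  check_features(object$guard, newdata)
  Xs <- standardize_apply(newdata, object$scaling)
  K <- rbf_kernel(Xs, object$X_train, object$gamma)
  drop(K %*% object$coefficients) + object$b
}

#' Serialize / restore a fitted model as JSON
#'
#' Stores the numeric state of a `plsr_model`, `svr_model`, `lssvm_model`
#' or `cotton_net` at full floating-point precision so `fit` and `predict`
#' can run as separate pipeline steps.
#'
#' @param model a fitted model object.
#' @param path JSON file path.
#' @return `path` (save) or the restored model object (load).
#' @export
save_model <- function(model, path) {
  cls <- class(model)[1L]
  if (!cls %in% c("plsr_model", "svr_model", "lssvm_model", "cotton_net"))
    stop("unsupported model class: ", cls)
  payload <- unclass(model)
  payload$.class <- cls
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL
  if (is.null(cls)) stop("not a model artifact (missing .class)")
  for (f in c("X_train")) if (!is.null(obj[[f]])) obj[[f]] <- as.matrix(obj[[f]])
  if (cls == "cotton_net") {
    obj$params <- lapply(obj$params, function(w)
      if (is.list(w) || is.matrix(w)) as.matrix(w) else as.numeric(w))
  }
  structure(obj, class = cls)
}
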