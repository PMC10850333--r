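#' Cotton-Net architecture specification
#'
#' The network has five computational stages: three 1-D convolutions with
#' 16, 64 and 48 kernels (activation after each), one average pooling
#' stage, and one fully connected layer with a single output node for the
#' impurity fraction. Convolutions use stride 1 and zero "same" padding so
#' the 125-channel signal keeps its length until pooling; pooling is
#' non-overlapping (window = stride).
#'
#' @param input_length spectrum length (default 125 channels).
#' @param conv_channels integer vector of three kernel counts.
#' @param kernel_size odd convolution kernel width.
#' @param pool_window,pool_stride average-pooling geometry; must be equal
#'   (non-overlapping pooling).
#' @param activation `"selu"`, `"relu"` or `"sigmoid"`.
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(input_length = 125L, conv_channels = c(16L, 64L, 48L),
                         kernel_size = 3L, pool_window = 2L, pool_stride = 2L,
                         activation = c("selu", "relu", "sigmoid")) {
  activation <- match.arg(activation)
  input_length <- as.integer(input_length)
  conv_channels <- as.integer(conv_channels)
  kernel_size <- as.integer(kernel_size)
  if (length(conv_channels) != 3L) stop("exactly three conv stages required")
  if (kernel_size %% 2L == 0L) stop("kernel_size must be odd (same padding)")
  if (pool_window != pool_stride)
    stop("only non-overlapping pooling (window == stride) is supported")
  pooled <- input_length %/% as.integer(pool_stride)
  if (input_length < kernel_size || pooled < 1L)
    stop(sprintf("input_length %d is below the receptive-field minimum",
                 input_length))
  structure(list(input_length = input_length, conv_channels = conv_channels,
                 kernel_size = kernel_size, pool_window = as.integer(pool_window),
                 pool_stride = as.integer(pool_stride),
                 pooled_length = pooled, activation = activation),
            class = "network_spec")
}

#' Cotton-Net training configuration
#'
#' Defaults follow the study's training setup: Adam optimizer, learning
#' rate 0.001, at most 200 epochs, mini-batches of 8. The default loss is
#' the logarithm of the mean squared error (the formula printed for the
#' "MSLE" loss), stabilized by `epsilon`; a conventional MSLE and plain MSE
#' are available as variants.
#'
#' @param learning_rate Adam step size.
#' @param max_epochs maximum training epochs.
#' @param batch_size mini-batch size.
#' @param loss_variant `"paper_log_mse"`, `"standard_msle"` or `"mse"`.
#' @param seed RNG seed for initialization and batch shuffling.
#' @param epsilon loss stabilizer added to the MSE before the log.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, max_epochs = 200L,
                         batch_size = 8L,
                         loss_variant = c("paper_log_mse", "standard_msle",
                                          "mse"),
                         seed = 1L, epsilon = 1e-8) {
  loss_variant <- match.arg(loss_variant)
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (max_epochs < 1L) stop("max_epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 loss_variant = loss_variant, seed = as.integer(seed),
                 epsilon = epsilon),
            class = "train_config")
}

SELU_LAMBDA <- 1.0507009873554804934193349852946
SELU_ALPHA <- 1.6732632423543772848170429916717

act_forward <- function(x, type) {
  switch(type,
         selu = {
           neg <- x <= 0
           out <- x
           out[neg] <- SELU_ALPHA * (exp(x[neg]) - 1)
           SELU_LAMBDA * out
         },
         relu = {
           out <- x
           out[out < 0] <- 0
           out
         },
         sigmoid = 1 / (1 + exp(-x)))
}

act_grad <- function(x, type) {
  switch(type,
         selu = {
           neg <- x <= 0
           out <- array(SELU_LAMBDA, dim(x))
           out[neg] <- SELU_LAMBDA * SELU_ALPHA * exp(x[neg])
           out
         },
         relu = {
           out <- array(0, dim(x))
           out[x > 0] <- 1
           out
         },
         sigmoid = {
           s <- 1 / (1 + exp(-x))
           s * (1 - s)
         })
}

# Activations travel as (C, L*B) matrices: channel-major, the L positions
# of sample b occupying the contiguous column block (b-1)*L + 1:L. The
# stride-1 same-padding convolution is an im2col matrix product; column
# index vectors for the k shifted copies are precomputed per (L, B).
conv_indices <- function(L, B, k) {
  h <- (k - 1L) %/% 2L
  Lp2 <- L + 2L * h
  inner <- as.vector(outer(h + seq_len(L), (seq_len(B) - 1L) * Lp2, `+`))
  shifts <- lapply(seq_len(k), function(j)
    as.vector(outer((j - 1L) + seq_len(L), (seq_len(B) - 1L) * Lp2, `+`)))
  list(k = k, padcols = Lp2 * B, inner = inner, shifts = shifts)
}

conv_forward <- function(A, W, b, ix) {
  C <- nrow(A)
  Apad <- matrix(0, C, ix$padcols)
  Apad[, ix$inner] <- A
  M <- matrix(0, C * ix$k, ncol(A))
  for (j in seq_len(ix$k))
    M[(j - 1L) * C + seq_len(C), ] <- Apad[, ix$shifts[[j]]]
  list(Z = W %*% M + b, M = M)
}

conv_backward <- function(dZ, W, M, C, ix) {
  dW <- tcrossprod(dZ, M)
  db <- rowSums(dZ)
  dM <- crossprod(W, dZ)
  dApad <- matrix(0, C, ix$padcols)
  for (j in seq_len(ix$k))
    dApad[, ix$shifts[[j]]] <- dApad[, ix$shifts[[j]]] +
      dM[(j - 1L) * C + seq_len(C), , drop = FALSE]
  list(dW = dW, db = db, dA = dApad[, ix$inner, drop = FALSE])
}

pool_indices <- function(L, B, w) {
  Lp <- L %/% w
  lapply(seq_len(w), function(j)
    as.vector(outer((seq_len(Lp) - 1L) * w + j, (seq_len(B) - 1L) * L, `+`)))
}

pool_forward <- function(A, px) {
  P <- A[, px[[1L]], drop = FALSE]
  for (j in seq_along(px)[-1L]) P <- P + A[, px[[j]], drop = FALSE]
  P / length(px)
}

pool_backward <- function(dP, px, C, LB) {
  dA <- matrix(0, C, LB)
  w <- length(px)
  for (j in seq_len(w)) dA[, px[[j]]] <- dP / w
  dA
}

init_sd <- function(activation, fan_in, fan_out) {
  switch(activation,
         selu = sqrt(1 / fan_in),       # LeCun normal (self-normalizing)
         relu = sqrt(2 / fan_in),       # Kaiming/He normal
         sigmoid = sqrt(2 / (fan_in + fan_out)))  # Xavier/Glorot normal
}

#' Build an initialized Cotton-Net
#'
#' Allocates and initializes all weights. The initialization scheme is
#' paired to the activation: LeCun normal for SELU, Kaiming normal for
#' ReLU, Xavier normal for Sigmoid; biases start at zero.
#'
#' @param spec a [network_spec()].
#' @param seed RNG seed for the weight draw; `NULL` uses the current RNG
#'   state (as [train_cotton_net()] does inside its seeded scope).
#' @return Object of class `cotton_net` with fields `spec` and `params`.
#' @export
build_cotton_net <- function(spec = network_spec(), seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  draw <- function() {
    k <- spec$kernel_size
    ch <- c(1L, spec$conv_channels)
    params <- list()
    for (i in 1:3) {
      fan_in <- ch[i] * k
      fan_out <- ch[i + 1L] * k
      sd <- init_sd(spec$activation, fan_in, fan_out)
      params[[paste0("W", i)]] <-
        matrix(stats::rnorm(ch[i + 1L] * fan_in, 0, sd), ch[i + 1L], fan_in)
      params[[paste0("b", i)]] <- numeric(ch[i + 1L])
    }
    nf <- spec$conv_channels[3L] * spec$pooled_length
    params$W4 <- matrix(stats::rnorm(nf, 0, init_sd(spec$activation, nf, 1L)),
                        1L, nf)
    params$b4 <- 0
    params
  }
  params <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(list(spec = spec, params = params, history = NULL),
            class = "cotton_net")
}

#' Count trainable parameters
#'
#' @param net a `cotton_net`.
#' @return Total number of weights and biases.
#' @export
count_parameters <- function(net) {
  sum(vapply(net$params, length, integer(1L)))
}

net_forward <- function(net, X, cache = FALSE) {
  spec <- net$spec
  pr <- net$params
  B <- nrow(X); L <- spec$input_length
  if (ncol(X) != L)
    stop(sprintf("input length mismatch: expected %d channels, got %d",
                 L, ncol(X)))
  ix <- conv_indices(L, B, spec$kernel_size)
  px <- pool_indices(L, B, spec$pool_window)
  A0 <- matrix(t(X), 1L)                       # (1, L*B)
  c1 <- conv_forward(A0, pr$W1, pr$b1, ix)
  A1 <- act_forward(c1$Z, spec$activation)
  c2 <- conv_forward(A1, pr$W2, pr$b2, ix)
  A2 <- act_forward(c2$Z, spec$activation)
  c3 <- conv_forward(A2, pr$W3, pr$b3, ix)
  A3 <- act_forward(c3$Z, spec$activation)
  P <- pool_forward(A3, px)
  flat <- matrix(P, spec$conv_channels[3L] * spec$pooled_length, B)
  yhat <- drop(pr$W4 %*% flat) + pr$b4
  if (!cache) return(yhat)
  list(yhat = yhat, ix = ix, px = px, c1 = c1, c2 = c2, c3 = c3,
       flat = flat, B = B)
}

net_backward <- function(net, cache, dyhat) {
  spec <- net$spec
  pr <- net$params
  ix <- cache$ix; px <- cache$px
  L <- spec$input_length
  gr <- list()
  gr$W4 <- matrix(drop(cache$flat %*% dyhat), 1L)
  gr$b4 <- sum(dyhat)
  dflat <- crossprod(pr$W4, matrix(dyhat, 1L))
  dP <- matrix(dflat, spec$conv_channels[3L],
               spec$pooled_length * cache$B)
  dZ3 <- pool_backward(dP, px, spec$conv_channels[3L], L * cache$B) *
    act_grad(cache$c3$Z, spec$activation)
  b3 <- conv_backward(dZ3, pr$W3, cache$c3$M, spec$conv_channels[2L], ix)
  gr$W3 <- b3$dW; gr$b3 <- b3$db
  dZ2 <- b3$dA * act_grad(cache$c2$Z, spec$activation)
  b2 <- conv_backward(dZ2, pr$W2, cache$c2$M, spec$conv_channels[1L], ix)
  gr$W2 <- b2$dW; gr$b2 <- b2$db
  dZ1 <- b2$dA * act_grad(cache$c1$Z, spec$activation)
  b1 <- conv_backward(dZ1, pr$W1, cache$c1$M, 1L, ix)
  gr$W1 <- b1$dW; gr$b1 <- b1$db
  gr
}

#' Training losses for Cotton-Net
#'
#' `paper_log_mse` is the loss formula exactly as the study prints it --
#' the natural logarithm of the mean squared residual -- stabilized with
#' `epsilon` so a perfect fit does not produce `-Inf`. `standard_msle` is
#' the conventional mean squared logarithmic error
#' `mean((log(1 + yhat) - log(1 + y))^2)` that usually goes by that name,
#' and `mse` is the plain mean squared residual.
#'
#' @param yhat predictions.
#' @param y observed values.
#' @param variant loss variant.
#' @param epsilon stabilizer for `paper_log_mse`.
#' @return Scalar loss (natural log throughout).
#' @export
msle_loss <- function(yhat, y,
                      variant = c("paper_log_mse", "standard_msle", "mse"),
                      epsilon = 1e-8) {
  variant <- match.arg(variant)
  if (!length(y) || length(y) != length(yhat))
    stop("yhat and y must be equal-length and non-empty")
  r <- yhat - y
  switch(variant,
         paper_log_mse = log(mean(r^2) + epsilon),
         standard_msle = {
           if (any(yhat <= -1) || any(y <= -1))
             stop("standard_msle requires yhat and y > -1")
           mean((log1p(yhat) - log1p(y))^2)
         },
         mse = mean(r^2))
}

loss_grad <- function(yhat, y, variant, epsilon) {
  n <- length(y)
  r <- yhat - y
  switch(variant,
         paper_log_mse = 2 * r / n / (mean(r^2) + epsilon),
         standard_msle = 2 * (log1p(yhat) - log1p(y)) / (1 + yhat) / n,
         mse = 2 * r / n)
}

#' Train Cotton-Net
#'
#' Mini-batch Adam training with the configured loss. Deterministic for a
#' given seed (pure-R single-threaded arithmetic): initialization, batch
#' shuffling and all updates run inside one seeded RNG scope. The final-
#' epoch weights are the model; no early stopping is applied.
#'
#' @param x a [spectra_set()] or a numeric matrix of (pretreated) spectra.
#' @param y target vector (taken from `x` when it is a `spectra_set`).
#' @param split optional [split_indices()]; training uses `split$train` and
#'   per-epoch validation loss is recorded on `split$test`.
#' @param spec a [network_spec()].
#' @param config a [train_config()].
#' @return A `cotton_net` whose `history` is a data frame with one row per
#'   epoch (`epoch`, `train_loss`, and `val_loss` when `split` is given).
#' @export
train_cotton_net <- function(x, y = NULL, split = NULL,
                             spec = network_spec(),
                             config = train_config()) {
  if (inherits(x, "spectra_set")) {
    if (is.null(y)) y <- x$target
    x <- x$reflectance
  }
  X <- as.matrix(x)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(x)")
  if (ncol(X) != spec$input_length)
    stop(sprintf("input length mismatch: spec expects %d, data has %d",
                 spec$input_length, ncol(X)))
  tr_idx <- if (is.null(split)) seq_len(nrow(X)) else split$train
  va_idx <- if (is.null(split)) integer(0) else split$test
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  n_tr <- nrow(Xtr)

  withr::with_seed(config$seed, {
    net <- build_cotton_net(spec, seed = NULL)
    m_state <- lapply(net$params, function(w) w * 0)
    v_state <- lapply(net$params, function(w) w * 0)
    beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
    step <- 0L
    hist_tr <- numeric(config$max_epochs)
    hist_va <- numeric(config$max_epochs)

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      starts <- seq(1L, n_tr, by = config$batch_size)
      batch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n_tr)]
        cache <- net_forward(net, Xtr[idx, , drop = FALSE], cache = TRUE)
        l <- msle_loss(cache$yhat, ytr[idx], config$loss_variant,
                       config$epsilon)
        if (!is.finite(l))
          stop(sprintf("non-finite training loss at epoch %d", epoch))
        batch_losses[bi] <- l
        gr <- net_backward(net, cache,
                           loss_grad(cache$yhat, ytr[idx],
                                     config$loss_variant, config$epsilon))
        step <- step + 1L
        for (nm in names(net$params)) {
          g <- gr[[nm]]
          m_state[[nm]] <- beta1 * m_state[[nm]] + (1 - beta1) * g
          v_state[[nm]] <- beta2 * v_state[[nm]] + (1 - beta2) * g^2
          mhat <- m_state[[nm]] / (1 - beta1^step)
          vhat <- v_state[[nm]] / (1 - beta2^step)
          net$params[[nm]] <- net$params[[nm]] -
            config$learning_rate * mhat / (sqrt(vhat) + adam_eps)
        }
      }
      hist_tr[epoch] <- mean(batch_losses)
      if (length(va_idx))
        hist_va[epoch] <- msle_loss(net_forward(net, X[va_idx, , drop = FALSE]),
                                    y[va_idx], config$loss_variant,
                                    config$epsilon)
    }
    net$history <- if (length(va_idx)) {
      data.frame(epoch = seq_len(config$max_epochs), train_loss = hist_tr,
                 val_loss = hist_va)
    } else {
      data.frame(epoch = seq_len(config$max_epochs), train_loss = hist_tr)
    }
    net$config <- config
    net
  })
}

#' Predict with a trained Cotton-Net
#'
#' Deterministic forward pass in evaluation mode.
#'
#' @param model a `cotton_net`.
#' @param X matrix of spectra with `spec$input_length` columns.
#' @return Numeric vector of predictions, one per row of `X`.
#' @export
predict_cotton_net <- function(model, X) {
  stopifnot(inherits(model, "cotton_net"))
  net_forward(model, as.matrix(X))
}

#' @export
predict.cotton_net <- function(object, newdata, ...) {
  predict_cotton_net(object, newdata)
}

#' Activation-function ablation grid
#'
#' Trains Cotton-Net on full-spectrum data for each of the three
#' pretreatments crossed with the three activations, reporting R_C, RMSE_C,
#' R_P and RMSE_P per cell -- the 9-row structure of the study's ablation
#' table. The same training configuration (and seed) is used in every cell
#' so that differences reflect only pretreatment and activation.
#'
#' @param data a [spectra_set()] of raw spectra.
#' @param split optional [split_indices()]; computed by [spxy_split()] on
#'   the raw spectra (180/230 train fraction) when omitted.
#' @param config a [train_config()].
#' @param preprocessors pretreatments to cross with activations.
#' @param activations activations to test.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters for `"sg"`.
#' @return Data frame with columns `model`, `preprocess`, `activation`,
#'   `r_c`, `rmse_c`, `r_p`, `rmse_p`.
#' @export
run_activation_ablation <- function(data, split = NULL,
                                    config = train_config(),
                                    preprocessors = c("sg", "normalization",
                                                      "snv"),
                                    activations = c("selu", "relu", "sigmoid"),
                                    sg_window = 11L, sg_polyorder = 2L) {
  validate_spectra_set(data)
  if (is.null(split))
    split <- spxy_split(data$reflectance, data$target,
                        round(nrow(data$reflectance) * 180 / 230))
  labels <- c(sg = "SG", normalization = "Normalization", snv = "SNV",
              selu = "SELU", relu = "ReLU", sigmoid = "Sigmoid")
  rows <- list()
  for (pre in preprocessors) {
    Xp <- preprocess_spectra(data$reflectance, pre,
                             sg_window = sg_window,
                             sg_polyorder = sg_polyorder)
    for (act in activations) {
      spec <- network_spec(input_length = ncol(Xp), activation = act)
      net <- train_cotton_net(Xp, data$target, split, spec, config)
      ev <- eval_report(data$target[split$train],
                        predict_cotton_net(net, Xp[split$train, , drop = FALSE]),
                        data$target[split$test],
                        predict_cotton_net(net, Xp[split$test, , drop = FALSE]))
      rows[[length(rows) + 1L]] <-
        data.frame(model = paste(labels[[pre]], "+", labels[[act]]),
                   preprocess = pre, activation = act,
                   r_c = ev$r_c, rmse_c = ev$rmse_c,
                   r_p = ev$r_p, rmse_p = ev$rmse_p)
    }
  }
  do.call(rbind, rows)
}
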