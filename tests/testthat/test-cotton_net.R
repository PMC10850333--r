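test_that("forward pass honours the architecture contract", {
  net <- build_cotton_net(network_spec(), seed = 1)
  expect_identical(net$spec$conv_channels, c(16L, 64L, 48L))
  X <- matrix(runif(4 * 125), 4, 125)
  out <- predict_cotton_net(net, X)
  expect_length(out, 4)
  expect_true(all(is.finite(out)))
  expect_error(predict_cotton_net(net, X[, 1:100]), "length mismatch")
})

test_that("parameter count equals the closed-form sum", {
  net <- build_cotton_net(network_spec(), seed = 2)
  closed <- (1L * 16L * 3L + 16L) + (16L * 64L * 3L + 64L) +
    (64L * 48L * 3L + 48L) + (48L * (125L %/% 2L) + 1L)
  expect_identical(count_parameters(net), closed)
})

test_that("im2col forward equals a naive per-position convolution oracle", {
  spec <- network_spec(input_length = 11, conv_channels = c(2L, 3L, 2L))
  for (act in c("selu", "relu", "sigmoid")) {
    spec$activation <- act
    net <- build_cotton_net(spec, seed = 5)
    set.seed(6)
    X <- matrix(rnorm(3 * 11), 3, 11)
    expect_equal(predict_cotton_net(net, X),
                 apply(X, 1, function(x) oracle_net_forward(net, x)),
                 tolerance = 1e-12, info = act)
  }
})

test_that("row permutation of a batch permutes outputs identically", {
  net <- build_cotton_net(network_spec(), seed = 3)
  X <- matrix(runif(6 * 125), 6, 125)
  out <- predict_cotton_net(net, X)
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(predict_cotton_net(net, X[perm, ]), out[perm],
               tolerance = 1e-12)
  # batch prediction equals concatenated single-sample predictions
  expect_equal(vapply(1:6, function(i)
    predict_cotton_net(net, X[i, , drop = FALSE]), numeric(1)),
    out, tolerance = 1e-12)
})

test_that("loss variants match their formulas", {
  expect_equal(msle_loss(c(1, -1), c(0, 0), "paper_log_mse", 0), 0)
  expect_equal(msle_loss(c(2, 4), c(0, 2), "paper_log_mse", 0), log(4))
  expect_equal(msle_loss(c(0.1, 0.2), c(0.1, 0.2), "standard_msle"), 0)
  expect_equal(msle_loss(c(1, 3), c(0, 1), "mse"), 2.5)
  expect_error(msle_loss(numeric(0), numeric(0)), "non-empty")
  expect_error(msle_loss(c(-2, 0), c(0, 0), "standard_msle"), "> -1")

  # paper_log_mse is strictly increasing in the mse
  set.seed(51)
  mses <- sort(vapply(1:20, function(i) mean(rnorm(10)^2), numeric(1)))
  losses <- log(mses + 1e-8)
  expect_true(all(diff(losses) > 0))
})

test_that("backprop matches finite-difference gradients", {
  spec <- network_spec(input_length = 12, conv_channels = c(2L, 3L, 2L))
  net <- build_cotton_net(spec, seed = 7)
  set.seed(8)
  X <- matrix(rnorm(3 * 12), 3, 12)
  y <- runif(3, 0.03, 0.2)
  cache <- cottonir:::net_forward(net, X, cache = TRUE)
  gr <- cottonir:::net_backward(net, cache,
                                cottonir:::loss_grad(cache$yhat, y,
                                                     "paper_log_mse", 1e-8))
  h <- 1e-6
  for (nm in names(net$params)) {
    for (i in seq_len(min(4, length(net$params[[nm]])))) {
      n2 <- net
      n2$params[[nm]][i] <- n2$params[[nm]][i] + h
      lp <- msle_loss(cottonir:::net_forward(n2, X), y)
      n2$params[[nm]][i] <- n2$params[[nm]][i] - 2 * h
      lm0 <- msle_loss(cottonir:::net_forward(n2, X), y)
      num <- (lp - lm0) / (2 * h)
      ana <- gr[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-8, abs(num), abs(ana)), 1e-4)
    }
  }
})

test_that("training defaults echo the study configuration", {
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 0.001)
  expect_identical(cfg$max_epochs, 200L)
  expect_identical(cfg$batch_size, 8L)
  expect_identical(cfg$loss_variant, "paper_log_mse")
})

test_that("training is bit-reproducible and records a full history", {
  ds <- generate_dataset(synthetic_config(n_samples = 40, seed = 9))
  Xn <- minmax_normalize(ds$reflectance)
  sp <- spxy_split(ds$reflectance, ds$target, 30)
  cfg <- train_config(max_epochs = 3, seed = 11)
  a <- train_cotton_net(Xn, ds$target, sp, network_spec(), cfg)
  b <- train_cotton_net(Xn, ds$target, sp, network_spec(), cfg)
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
  expect_identical(nrow(a$history), 3L)
  expect_true(all(is.finite(a$history$train_loss)))
  expect_true(all(c("train_loss", "val_loss") %in% names(a$history)))
})

test_that("a numerically overflowing run aborts naming the epoch", {
  X <- matrix(1e200, 8, 125)   # overflows to Inf inside the conv stack
  spec <- network_spec(activation = "relu")
  cfg <- train_config(loss_variant = "mse", max_epochs = 3, seed = 1)
  expect_error(train_cotton_net(X, runif(8), NULL, spec, cfg),
               "non-finite training loss at epoch [0-9]+")
})
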