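test_that("projection chains visit orthogonal columns by descending norm", {
  # orthogonal columns with distinct norms: projections leave them unchanged
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:4]
  X <- Q %*% diag(c(3, 1, 4, 2))
  for (start in 1:4) {
    chain <- successive_projection(X, start, 4)
    expect_identical(chain[1], start)
    expect_identical(chain[-1], setdiff(order(-c(3, 1, 4, 2)), start))
  }
})

test_that("a duplicated start column has zero residual and is deferred", {
  set.seed(21)
  X <- matrix(rnorm(8 * 4), 8, 4)
  X[, 3] <- X[, 1]                       # duplicate of column 1
  chain <- successive_projection(X, 1, 4)
  expect_identical(chain[4], 3L)         # picked only when nothing else left
})

test_that("projection chains match the Gram-Schmidt oracle", {
  for (case in 1:15) {
    set.seed(400 + case)
    X <- matrix(rnorm(8 * 5), 8, 5)
    Xc <- sweep(X, 2, colMeans(X))
    start <- sample(5, 1)
    expect_identical(successive_projection(Xc, start, 5),
                     oracle_spa_chain(Xc, start, 5),
                     info = sprintf("case %d", case))
  }
})

test_that("projection chain guards its preconditions", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(successive_projection(X, 1, 4), "chain length")
  X0 <- cbind(0, X)
  expect_error(successive_projection(X0, 1, 3), "zero-variance start")
})

test_that("SPA with a forced single winner selects it", {
  set.seed(22)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- 3 * X[, 3]
  sel <- spa_select(X, y, 1, 1)
  expect_identical(sel$selected, 3L)
  expect_identical(sel$method, "spa")
})

test_that("SPA beats (or ties) full-spectrum MLR on the same folds", {
  set.seed(23)
  X <- matrix(rnorm(50 * 12), 50, 12)
  y <- X[, 2] - 2 * X[, 9] + rnorm(50, 0, 0.2)
  sel <- spa_select(X, y, 1, 8)
  expect_lte(min(sel$scores), oracle_mlr_cv_rmse(X, y, 1:12) + 1e-12)
})

test_that("random frog echoes the study defaults and validates config", {
  fm <- formals(random_frog_select)
  expect_identical(eval(fm$n_iter), 1000L)
  expect_identical(eval(fm$q_init), 5L)
  expect_true(eval(fm$center))
  X <- matrix(rnorm(40), 10, 4)
  expect_error(random_frog_select(X, rnorm(10), q_init = 5), "q_init")
  expect_error(random_frog_select(X, rnorm(10), n_iter = 0, q_init = 2),
               "n_iter")
})

test_that("random frog is seed-reproducible with valid probabilities", {
  d <- make_planted(60, 15, c(2, 9), c(1.5, -1), 0.3, seed = 24)
  a <- random_frog_select(d$X, d$y, n_iter = 120, q_init = 3, seed = 42)
  b <- random_frog_select(d$X, d$y, n_iter = 120, q_init = 3, seed = 42)
  expect_identical(a, b)
  expect_true(all(a$scores >= 0 & a$scores <= 1))
  # inclusion tallies are integer counts bounded by the iteration total
  counts <- a$scores * 120
  expect_equal(counts, round(counts), tolerance = 1e-9)
  expect_true(all(!duplicated(a$selected)))
  expect_true(all(a$selected >= 1 & a$selected <= 15))
})

test_that("random frog ranks planted variables on top at low noise", {
  d <- make_planted(80, 20, c(4, 11, 17), c(1, 1, -1), 0.05, seed = 25)
  sel <- random_frog_select(d$X, d$y, n_iter = 250, q_init = 3, seed = 7)
  expect_true(all(c(4, 11, 17) %in% order(-sel$scores)[1:5]))
})
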