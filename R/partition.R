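#' SPXY sample-set partitioning
#'
#' Splits samples into calibration and test sets by the joint X-Y distance:
#' `d(i,j) = dx(i,j)/max(dx) + dy(i,j)/max(dy)` with `dx` the Euclidean
#' distance between spectra and `dy = |y_i - y_j|`. Selection is the
#' Kennard-Stone maximin rule on `d`: seed with the pair attaining the
#' maximum joint distance, then repeatedly add the sample whose minimum
#' joint distance to the already-selected set is largest, until `n_train`
#' samples are selected; the remainder forms the test set. Fully
#' deterministic; ties are broken toward the smallest index.
#'
#' When `y` is constant, `max(dy) == 0` and the y-term is defined as 0, so
#' the split degenerates to plain Kennard-Stone on the spectral distance.
#'
#' @param X numeric matrix of spectra (rows = samples), or a
#'   [spectra_set()] (in which case `y` is taken from it).
#' @param y numeric target vector.
#' @param n_train number of calibration samples (`1 <= n_train <= n - 1`),
#'   or a fraction in (0, 1) interpreted as `round(n * fraction)`.
#' @return A [split_indices()] object.
#' @export
spxy_split <- function(X, y = NULL, n_train) {
  if (inherits(X, "spectra_set")) {
    if (is.null(y)) y <- X$target
    X <- X$reflectance
  }
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 samples")
  if (anyNA(X) || !all(is.finite(X)) || anyNA(y) || !all(is.finite(y)))
    stop("X and y must be finite")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (length(n_train) != 1L || !is.finite(n_train))
    stop("n_train must be a single number")
  if (n_train > 0 && n_train < 1) n_train <- round(n * n_train)
  n_train <- as.integer(n_train)
  if (n_train < 1L || n_train > n - 1L)
    stop(sprintf("n_train must lie in [1, %d]", n - 1L))

  dx <- as.matrix(stats::dist(X))
  dy <- abs(outer(y, y, `-`))
  mx <- max(dx); my <- max(dy)
  if (mx == 0 && my == 0)
    stop("all samples identical in X and y: joint distance is degenerate")
  D <- (if (mx > 0) dx / mx else dx) + (if (my > 0) dy / my else dy)

  hits <- which(D == max(D), arr.ind = TRUE)
  hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  pair <- as.integer(hits[1L, ])

  selected <- if (n_train == 1L) pair[1L] else pair
  while (length(selected) < n_train) {
    remaining <- setdiff(seq_len(n), selected)
    dmin <- apply(D[remaining, selected, drop = FALSE], 1L, min)
    selected <- c(selected, remaining[which.max(dmin)])
  }
  split_indices(selected, setdiff(seq_len(n), selected))
}
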