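#' Min-max normalization of reflectance spectra
#'
#' Rescales each slice (spectrum or wavelength channel) to `[0, 1]` via
#' `(x - min(x)) / (max(x) - min(x))`. The default axis is `per_spectrum`:
#' each sample's spectrum is scaled over its own channels, matching the
#' per-spectrum convention of SNV. `per_wavelength` scales each channel
#' column instead, and accepts precomputed training-set statistics via
#' `stats` so test data can be transformed without leakage (in which case
#' values may legitimately fall outside `[0, 1]`).
#'
#' @param X numeric matrix, rows are spectra.
#' @param axis `"per_spectrum"` (default) or `"per_wavelength"`.
#' @param stats optional `list(min=, max=)` of per-column statistics from a
#'   training set; only meaningful with `axis = "per_wavelength"`.
#' @return Matrix of the same shape.
#' @export
minmax_normalize <- function(X, axis = c("per_spectrum", "per_wavelength"),
                             stats = NULL) {
  axis <- match.arg(axis)
  X <- as.matrix(X)
  if (anyNA(X) || !all(is.finite(X)))
    stop("minmax_normalize: input contains missing or non-finite values")
  if (axis == "per_spectrum") {
    lo <- apply(X, 1L, min)
    hi <- apply(X, 1L, max)
    deg <- which(hi == lo)
    if (length(deg))
      stop(sprintf("degenerate range (max == min) in row %d", deg[1L]))
    (X - lo) / (hi - lo)
  } else {
    if (is.null(stats)) stats <- minmax_stats(X)
    lo <- stats$min; hi <- stats$max
    if (length(lo) != ncol(X) || length(hi) != ncol(X))
      stop("per-wavelength stats length does not match column count")
    deg <- which(hi == lo)
    if (length(deg))
      stop(sprintf("degenerate range (max == min) in column %d", deg[1L]))
    sweep(sweep(X, 2L, lo, `-`), 2L, hi - lo, `/`)
  }
}

#' @rdname minmax_normalize
#' @export
minmax_stats <- function(X) {
  X <- as.matrix(X)
  list(min = apply(X, 2L, min), max = apply(X, 2L, max))
}

#' Standard normal variate transform
#'
#' Centers each spectrum to zero mean and scales it to unit sample standard
#' deviation (n - 1 denominator). SNV suppresses the multiplicative scatter
#' and additive baseline offsets caused by the loose, gappy packing of seed
#' cotton in the sampling cell: it is exactly invariant to per-spectrum
#' transforms `x -> a x + c` with `a > 0`.
#'
#' @param X numeric matrix, rows are spectra with at least 2 channels.
#' @return Matrix of the same shape; each row has mean 0 and sample sd 1.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("snv: each spectrum needs at least 2 channels")
  if (anyNA(X) || !all(is.finite(X)))
    stop("snv: input contains missing or non-finite values")
  m <- rowMeans(X)
  s <- sqrt(rowSums((X - m)^2) / (ncol(X) - 1L))
  deg <- which(s == 0)
  if (length(deg))
    stop(sprintf("zero-variance spectrum in row %d", deg[1L]))
  (X - m) / s
}

# Per-position smoothing weights: row i of the returned p x p matrix holds
# the least-squares polynomial weights whose dot product with a spectrum
# gives the fitted value at channel i. Interior rows are the classical
# centered Savitzky-Golay weights; edge rows keep the full window anchored
# at the boundary and evaluate the fitted polynomial at the edge channel,
# so output length stays p and channel indexing stays aligned.
sg_weight_matrix <- function(p, window, polyorder) {
  h <- (window - 1L) %/% 2L
  S <- matrix(0, p, p)
  for (i in seq_len(p)) {
    start <- min(max(i - h, 1L), p - window + 1L)
    pos <- start:(start + window - 1L)
    A <- outer(pos - i, 0:polyorder, `^`)
    S[i, pos] <- solve(crossprod(A), t(A))[1L, ]
  }
  S
}

#' Savitzky-Golay smoothing
#'
#' Moving-window least-squares polynomial smoothing applied per spectrum.
#' Each output value is the window's fitted polynomial evaluated at the
#' window center; near the boundaries the window is anchored at the edge
#' (not shrunk) and the polynomial evaluated at the edge position, so the
#' output has the same length as the input. Exact for signals that are
#' polynomials of degree `<= polyorder`, and linear in the input.
#'
#' @param X numeric matrix, rows are spectra.
#' @param window odd window width `>= 3` and `<= ncol(X)`.
#' @param polyorder polynomial degree, `0 <= polyorder < window`.
#' @return Smoothed matrix of the same shape.
#' @export
savitzky_golay <- function(X, window = 11L, polyorder = 2L) {
  X <- as.matrix(X)
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window < 3L) stop("window must be >= 3")
  if (polyorder < 0L || polyorder >= window)
    stop("polyorder must satisfy 0 <= polyorder < window")
  if (window > ncol(X))
    stop(sprintf("window (%d) exceeds channel count (%d)", window, ncol(X)))
  if (anyNA(X) || !all(is.finite(X)))
    stop("savitzky_golay: input contains missing or non-finite values")
  S <- sg_weight_matrix(ncol(X), window, polyorder)
  X %*% t(S)
}

#' Apply a named pretreatment to a reflectance matrix
#'
#' Dispatcher over the three pretreatments compared in the study plus
#' `"none"`. All are stateless per spectrum except `per_wavelength`
#' min-max normalization, for which training statistics can be passed
#' through `stats`.
#'
#' @param X numeric matrix, rows are spectra.
#' @param method one of `"normalization"`, `"snv"`, `"sg"`, `"none"`.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters.
#' @param normalization_axis axis for min-max normalization.
#' @param stats optional training statistics for per-wavelength min-max.
#' @return Pretreated matrix of the same shape.
#' @export
preprocess_spectra <- function(X,
                               method = c("normalization", "snv", "sg", "none"),
                               sg_window = 11L, sg_polyorder = 2L,
                               normalization_axis = "per_spectrum",
                               stats = NULL) {
  method <- match.arg(method)
  switch(method,
         normalization = minmax_normalize(X, normalization_axis, stats),
         snv = snv(X),
         sg = savitzky_golay(X, sg_window, sg_polyorder),
         none = as.matrix(X))
}
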