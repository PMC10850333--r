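#' Construct a spectra set
#'
#' A `spectra_set` bundles an n x p reflectance matrix with its wavelength
#' grid (nm), a length-n target vector (impurity mass fraction) and unique
#' sample identifiers. All downstream stages (pretreatment, SPXY
#' partitioning, wavelength selection, modelling) operate on this container.
#' Reflectance is stored as measured; no absorbance (log 1/R) conversion is
#' applied anywhere in the package.
#'
#' @param reflectance numeric matrix, n samples x p channels, finite and
#'   non-negative.
#' @param wavelengths strictly increasing numeric vector of length p (nm).
#' @param target numeric vector of length n, the impurity mass fraction.
#' @param sample_ids character vector of n unique labels; defaults to
#'   `S001, S002, ...`.
#' @param pretreated set to `TRUE` for matrices that are no longer raw
#'   reflectance (e.g. SNV output), which relaxes the non-negativity
#'   invariant.
#' @return An object of class `spectra_set` with fields `reflectance`,
#'   `wavelengths`, `target`, `sample_ids`, `pretreated`.
#' @examples
#' s <- spectra_set(matrix(runif(20), 4, 5), seq(950, 1650, length.out = 5),
#'                  runif(4, 0.03, 0.2))
#' @export
spectra_set <- function(reflectance, wavelengths, target, sample_ids = NULL,
                        pretreated = FALSE) {
  if (!is.matrix(reflectance) || !is.numeric(reflectance))
    stop("`reflectance` must be a numeric matrix")
  n <- nrow(reflectance)
  p <- ncol(reflectance)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(n))
  out <- structure(
    list(reflectance = unname(reflectance),
         wavelengths = as.numeric(wavelengths),
         target = as.numeric(target),
         sample_ids = as.character(sample_ids),
         pretreated = isTRUE(pretreated)),
    class = "spectra_set")
  validate_spectra_set(out)
  out
}

#' Validate a spectra set
#'
#' Checks every structural invariant of the container: matching dimensions,
#' strictly increasing wavelengths, finite non-negative reflectance, finite
#' targets, and unique sample identifiers.
#'
#' @param x object to validate.
#' @return `x`, invisibly, if valid; otherwise an error describing the first
#'   violated invariant.
#' @export
validate_spectra_set <- function(x) {
  if (!inherits(x, "spectra_set")) stop("not a spectra_set")
  need <- c("reflectance", "wavelengths", "target", "sample_ids")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("spectra_set is missing field(s): ",
                         paste(miss, collapse = ", "))
  X <- x$reflectance
  n <- nrow(X); p <- ncol(X)
  if (length(x$target) == 0L) stop("target vector is required and non-empty")
  if (length(x$target) != n)
    stop(sprintf("target length (%d) != number of spectra (%d)",
                 length(x$target), n))
  if (length(x$sample_ids) != n)
    stop(sprintf("sample_ids length (%d) != number of spectra (%d)",
                 length(x$sample_ids), n))
  if (length(x$wavelengths) != p)
    stop(sprintf("wavelength grid length (%d) != number of channels (%d)",
                 length(x$wavelengths), p))
  if (p >= 2L && any(diff(x$wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (anyNA(X) || !all(is.finite(X)))
    stop("reflectance contains missing or non-finite values")
  if (!isTRUE(x$pretreated) && any(X < 0))
    stop("raw reflectance must be non-negative")
  if (anyNA(x$target) || !all(is.finite(x$target)))
    stop("target contains missing or non-finite values")
  if (anyDuplicated(x$sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(x$sample_ids[duplicated(x$sample_ids)]), collapse = ", "))
  invisible(x)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d spectra x %d channels (%.0f-%.0f nm)\n",
              nrow(x$reflectance), ncol(x$reflectance),
              min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf("  target (impurity fraction): %.4f-%.4f\n",
              min(x$target), max(x$target)))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$reflectance)

#' Construct train/test split indices
#'
#' @param train,test integer index vectors; must be disjoint, non-empty, and
#'   jointly cover `1:n` where `n = length(train) + length(test)`.
#' @return Object of class `split_indices` with sorted `train` and `test`.
#' @export
split_indices <- function(train, test) {
  train <- sort(as.integer(train)); test <- sort(as.integer(test))
  if (!length(train) || !length(test))
    stop("both train and test must be non-empty")
  n <- length(train) + length(test)
  if (length(intersect(train, test)))
    stop("train and test indices overlap")
  if (!identical(sort(c(train, test)), seq_len(n)))
    stop("train and test must partition 1:n")
  structure(list(train = train, test = test), class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("split_indices: %d train / %d test\n",
              length(x$train), length(x$test)))
  invisible(x)
}

#' Construct a wavelength selection result
#'
#' @param selected ordered integer vector of selected channel indices
#'   (1-based, unique, within `1:p`).
#' @param scores per-variable diagnostic: the cross-validated RMSE path for
#'   SPA, or the length-p selection-probability vector for random frog.
#' @param method tag, e.g. `"spa"` or `"frog"`.
#' @param p total number of channels (for range validation), optional.
#' @return Object of class `selection_result`.
#' @export
selection_result <- function(selected, scores = NULL, method = "unknown",
                             p = NULL) {
  selected <- as.integer(selected)
  if (anyDuplicated(selected)) stop("selected indices must be unique")
  if (any(selected < 1L)) stop("selected indices must be >= 1")
  if (!is.null(p) && any(selected > p))
    stop("selected indices exceed the number of channels")
  if (identical(method, "frog") && !is.null(scores) &&
      (any(scores < 0) || any(scores > 1)))
    stop("frog selection probabilities must lie in [0, 1]")
  structure(list(selected = selected, scores = scores, method = method),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result [%s]: %d variables\n  indices: %s\n",
              x$method, length(x$selected),
              paste(x$selected, collapse = ", ")))
  invisible(x)
}
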