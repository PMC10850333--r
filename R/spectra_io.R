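#' Read a spectra table from CSV
#'
#' The expected layout is one header row with a `sample_id` column
#' (optional), one target column (default `"impurity"`), and spectral
#' columns whose header tokens are the wavelengths in nm. Spectral columns
#' are recognised purely by their numeric headers, so metadata columns can
#' be mixed in freely.
#'
#' @param path CSV file path.
#' @param target_column name of the target column.
#' @param pretreated pass `TRUE` when reading a pretreated artifact (e.g.
#'   SNV output), which may legitimately contain negative values.
#' @return A validated [spectra_set()].
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, target_column = "impurity",
                         pretreated = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(nf) < 2L) stop("file must contain a header row and >= 1 sample")
  bad <- which(nf != nf[1L])
  if (length(bad))
    stop(sprintf("ragged CSV: row %d has %d fields, expected %d (header)",
                 bad[1L], nf[bad[1L]], nf[1L]))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        stringsAsFactors = FALSE)
  nms <- names(df)
  wl_num <- suppressWarnings(as.numeric(nms))
  spectral <- which(is.finite(wl_num))
  if (!length(spectral))
    stop("no spectral columns found (numeric wavelength headers expected)")
  if (!target_column %in% nms)
    stop(sprintf("missing target column '%s'", target_column))

  to_num <- function(col, colname) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !(trimws(col) %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("non-numeric cell at data row %d, column '%s': '%s'",
                   bad[1L], colname, col[bad[1L]]))
    nav <- which(is.na(v))
    if (length(nav))
      stop(sprintf("missing value at data row %d, column '%s'",
                   nav[1L], colname))
    v
  }

  X <- vapply(spectral, function(j) to_num(df[[j]], nms[j]),
              numeric(nrow(df)))
  if (!is.matrix(X)) X <- matrix(X, nrow = nrow(df))
  y <- to_num(df[[target_column]], target_column)
  ids <- if ("sample_id" %in% nms) df[["sample_id"]] else NULL
  if (!is.null(ids) && anyDuplicated(ids))
    stop("duplicate sample IDs in column 'sample_id': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  wl <- wl_num[spectral]
  ord <- order(wl)
  spectra_set(X[, ord, drop = FALSE], wl[ord], y, ids,
              pretreated = pretreated)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a spectra table to CSV
#'
#' Writes a CSV that [read_spectra()] reads back bit-for-bit: all numeric
#' values (including the wavelength headers) are rendered with 17
#' significant digits, enough to round-trip IEEE doubles exactly.
#'
#' @param data a valid [spectra_set()].
#' @param path output file path.
#' @param target_column header used for the target column.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(data, path, target_column = "impurity") {
  validate_spectra_set(data)
  header <- paste(c("sample_id", target_column, fmt17(data$wavelengths)),
                  collapse = ",")
  rows <- vapply(seq_len(nrow(data$reflectance)), function(i) {
    paste(c(data$sample_ids[i], fmt17(data$target[i]),
            fmt17(data$reflectance[i, ])), collapse = ",")
  }, character(1L))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Write / read a train-test split artifact
#'
#' JSON sidecar of the form `{"train":[...],"test":[...]}`. Indices are
#' 1-based (R convention) and the artifact says so in an `index_base` field.
#'
#' @param split a [split_indices()] object.
#' @param path JSON file path.
#' @return `path` (write) or a `split_indices` object (read).
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "split_indices"))
  jsonlite::write_json(list(train = split$train, test = split$test,
                            index_base = 1L),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$train) || is.null(obj$test))
    stop("split artifact must contain 'train' and 'test'")
  split_indices(obj$train, obj$test)
}

#' Write / read a wavelength selection artifact
#'
#' JSON sidecar of the form
#' `{"method":"spa","selected":[...],"wavelengths":[...],"scores":[...]}`.
#' `selected` holds 1-based channel indices; `wavelengths` the matching nm
#' values when a grid is supplied (what the instrument-facing reports use).
#'
#' @param sel a [selection_result()] object.
#' @param path JSON file path.
#' @param wavelengths optional nm grid used to annotate selected channels.
#' @return `path` (write) or a `selection_result` (read).
#' @export
write_selection <- function(sel, path, wavelengths = NULL) {
  stopifnot(inherits(sel, "selection_result"))
  obj <- list(method = sel$method, selected = sel$selected,
              index_base = 1L)
  if (!is.null(wavelengths)) obj$wavelengths <- wavelengths[sel$selected]
  if (!is.null(sel$scores)) obj$scores <- sel$scores
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$selected) || is.null(obj$method))
    stop("selection artifact must contain 'method' and 'selected'")
  selection_result(obj$selected, scores = obj$scores, method = obj$method)
}
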