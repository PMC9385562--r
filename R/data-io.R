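#' Read a delimited numeric matrix with row and column headers
#'
#' Reads a tab- or comma-delimited text matrix (one header row with column
#' names, one header column with row names) into a numeric matrix. Empty cells
#' or sentinel tokens become `NA`, which the package treats as unobserved
#' entries throughout (no loss, gradient, or metric ever touches them).
#'
#' @param path Path to the delimited text file.
#' @param sep Field separator. `NULL` (default) guesses from the file name and
#'   first line: `"\t"` unless the header contains more commas than tabs.
#' @param na Character vector of sentinel tokens for missing values, in
#'   addition to empty cells.
#' @param rows_are_samples If `FALSE`, the matrix is transposed after reading
#'   so that rows index samples.
#' @return A numeric matrix with `dimnames`; unobserved entries are `NA`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_matrix_delim(matrix(1:4, 2, dimnames = list(c("a", "b"), c("d1", "d2"))), tf)
#' read_matrix_delim(tf)
read_matrix_delim <- function(path, sep = NULL, na = c("NA", ""),
                              rows_are_samples = TRUE) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  if (is.null(sep)) {
    sep <- if (lengths(regmatches(first, gregexpr(",", first))) >
                 lengths(regmatches(first, gregexpr("\t", first)))) "," else "\t"
  }
  df <- tryCatch(
    read.table(path, sep = sep, header = TRUE, row.names = NULL,
               na.strings = na, check.names = FALSE, fill = FALSE,
               stringsAsFactors = FALSE, comment.char = "", quote = "\""),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  if (ncol(df) < 2L) stop("parse error in ", path, ": no data columns", call. = FALSE)
  rn <- as.character(df[[1L]])
  if (anyDuplicated(rn)) {
    stop("duplicate row headers in ", path, call. = FALSE)
  }
  cn <- colnames(df)[-1L]
  if (anyDuplicated(cn)) {
    stop("duplicate column headers in ", path, call. = FALSE)
  }
  x <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(x)) {
    x <- matrix(suppressWarnings(as.numeric(x)), nrow(df), ncol(df) - 1L)
  }
  dimnames(x) <- list(rn, cn)
  if (!rows_are_samples) x <- t(x)
  x
}

#' Write a numeric matrix as delimited text
#'
#' Inverse of [read_matrix_delim()]: writes the matrix with one header row and
#' one header column; `NA` entries are written as the `na` token. The
#' round trip preserves values, headers, and the missing mask.
#'
#' @param x Numeric matrix with `dimnames`.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @param na Token used for missing entries.
#' @return `path`, invisibly.
#' @export
write_matrix_delim <- function(x, path, sep = "\t", na = "NA") {
  stopifnot(is.matrix(x))
  if (is.null(rownames(x))) rownames(x) <- paste0("r", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("c", seq_len(ncol(x)))
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, na = na, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-tissue assignment table
#'
#' Reads a two-column delimited table (sample id, tissue label) and returns the
#' labels as a named character vector in the file's order.
#'
#' @inheritParams read_matrix_delim
#' @return Named character vector of tissue labels.
#' @export
read_tissue_table <- function(path, sep = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(sep)) {
    sep <- if (lengths(regmatches(first, gregexpr(",", first))) >
                 lengths(regmatches(first, gregexpr("\t", first)))) "," else "\t"
  }
  df <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (ncol(df) < 2L) stop("tissue table needs two columns (sample, tissue)",
                          call. = FALSE)
  if (anyDuplicated(df[[1L]])) stop("duplicate sample ids in ", path, call. = FALSE)
  setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
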