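# CSV I/O used by every table reader/writer.
#
# Dialect is fixed: UTF-8, comma separator, header row, "." decimal, no
# locale handling. Numeric cells are written with "%.17g" so a written table
# re-reads to bitwise-identical doubles (base write.csv's 15-significant-digit
# default is lossy).

.format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    sprintf("%.17g", v)
  }, character(1))
  out
}

.write_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- .format_num(out[[j]])
  }
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8"),
    error = function(e) stop("cannot write ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  invisible(path)
}

.read_csv <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

.require_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("schema error in ", table, ": missing column ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a tidy result table to CSV
#'
#' Results are written in a stable, documented column order with full-precision
#' numeric formatting, so that [read_results()] returns a table whose values
#' are identical to what was written (lossless round trip) and two runs of the
#' same pipeline produce byte-identical files.
#'
#' @param table a data.frame in tidy long format (one row per index tuple).
#' @param path output file path.
#' @return the path, invisibly.
#' @details Tables containing `NA`/`NaN` values are rejected: results must be
#'   complete before they are written.
#' @seealso [read_results()]
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  num <- vapply(table, is.numeric, logical(1))
  if (any(vapply(table[num], function(x) any(is.na(x)), logical(1)))) {
    stop("result table contains NA/NaN values; results must be complete",
         call. = FALSE)
  }
  .write_csv(table, path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  .read_csv(path)
}
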