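## Plain-text input/output: RFC-4180 CSV tables, JSON results and
## provenance files. All writers are deterministic so identical inputs give
## byte-identical files.

#' Write a data frame as CSV
#'
#' UTF-8, header row, no row names; deterministic formatting.
#'
#' @param x Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cell/trace/count CSV or TSV table
#'
#' @param path Input file; tab-separated when the extension is `.tsv`.
#' @return A data frame.
#' @export
read_table_csv <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Serialize an analysis result to JSON
#'
#' @param x A list or result object (coerced with `unclass`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(prepare_json(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

prepare_json <- function(x) {
  if (inherits(x, "qq_result")) {
    x <- unclass(x)
    x$points <- NULL  # per-cell detail stays in CSV outputs
  } else if (is.object(x) && !is.data.frame(x)) {
    x <- unclass(x)
  }
  if (is.list(x) && !is.data.frame(x)) x <- lapply(x, prepare_json)
  x
}

#' Echo simulation parameters to a JSON provenance file
#'
#' @param params A parameter object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  jsonlite::write_json(strip(params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
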