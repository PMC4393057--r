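#' Read a GEO series-matrix file
#'
#' Parses the tab-delimited GEO series-matrix dialect: metadata lines are
#' prefixed with `!`, the data block sits between `!series_matrix_table_begin`
#' and `!series_matrix_table_end` (both optional), its first row is a header
#' whose first column holds probe identifiers and remaining columns one sample
#' each. Empty cells and the tokens `NA` and `null` (case-insensitive, with or
#' without quotes) are read as missing. Values are ingested as deposited --
#' for two-channel arrays these are already log-ratios; no background
#' correction or within-array normalization is applied.
#'
#' @param path path to a series-matrix file.
#' @param species_label dataset label stored on the returned matrix.
#' @return An [expression_matrix()] with row and column order preserved from
#'   the file.
#' @seealso [write_series_matrix()] for the inverse operation.
#' @export
read_series_matrix <- function(path, species_label = "") {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "!") & nzchar(trimws(lines))
  data_lines <- lines[keep]
  if (length(data_lines) < 2L)
    stop("no data table found in ", path,
         " (need a header line and at least one probe row)")
  line_no <- which(keep)
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  header <- strip_quotes(fields[[1L]])
  ncol_expected <- length(header)
  if (ncol_expected < 2L)
    stop("header has fewer than 2 columns in ", path)
  widths <- lengths(fields[-1L])
  bad <- which(widths != ncol_expected)
  if (length(bad) > 0L)
    stop("ragged row at line ", line_no[bad[1L] + 1L], ": expected ",
         ncol_expected, " columns, found ", widths[bad[1L]])
  body <- fields[-1L]
  ids <- strip_quotes(vapply(body, `[[`, character(1L), 1L))
  cells <- vapply(body, function(f) parse_cells(f[-1L]),
                  numeric(ncol_expected - 1L))
  values <- if (is.matrix(cells)) t(cells) else matrix(cells, ncol = ncol_expected - 1L)
  expression_matrix(values, ids, header[-1L], species_label = species_label)
}

MISSING_TOKENS <- c("", "na", "null")

parse_cells <- function(x) {
  x <- strip_quotes(x)
  miss <- tolower(trimws(x)) %in% MISSING_TOKENS
  out <- suppressWarnings(as.numeric(x))
  bad <- !miss & is.na(out)
  if (any(bad))
    stop("non-numeric value that is not a missing token: '", x[which(bad)[1L]], "'")
  out[miss] <- NA_real_
  out
}

strip_quotes <- function(x) {
  x <- trimws(x)
  q <- nchar(x) >= 2L & startsWith(x, "\"") & endsWith(x, "\"")
  x[q] <- substr(x[q], 2L, nchar(x[q]) - 1L)
  x
}

#' Write a GEO-style series-matrix file
#'
#' Writes an [expression_matrix()] in the tab-delimited series-matrix dialect
#' that [read_series_matrix()] reads back. Values are written with 15
#' significant digits so a write/read round trip reproduces the matrix;
#' missing cells are written as `null`.
#'
#' @param m an `ExpressionMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series_matrix <- function(m, path) {
  stopifnot_em(m)
  vals <- format_num(m$values)
  vals[is.na(m$values)] <- "null"
  lines <- c(
    paste0("!Series_title\t\"", m$species_label, "\""),
    if (!is.null(m$group_labels))
      paste0("!Sample_characteristics_ch1\t",
             paste0("\"group: ", m$group_labels, "\"", collapse = "\t")),
    "!series_matrix_table_begin",
    paste(c("\"ID_REF\"", paste0("\"", sample_ids(m), "\"")), collapse = "\t"),
    paste(rownames(m$values),
          apply(vals, 1L, paste, collapse = "\t"), sep = "\t"),
    "!series_matrix_table_end")
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write file ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

format_num <- function(x) {
  out <- formatC(x, format = "g", digits = 15)
  dim(out) <- dim(x)
  out
}

#' Write a tab-delimited results table
#'
#' Emits pipeline result tables (CV tables, stability tables, overlap
#' summaries) as plain tab-delimited text with a header row. Stability-index
#' style numeric columns can be rounded to a fixed number of decimals to match
#' conventional reporting precision.
#'
#' @param rows a data.frame; all rows share the header.
#' @param path output path.
#' @param digits decimals used for numeric columns; `NA` writes full
#'   precision. Default 3, the usual precision for stability indices.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path, digits = 3) {
  if (!is.data.frame(rows)) {
    rows <- tryCatch(as.data.frame(rows, stringsAsFactors = FALSE),
                     error = function(e) stop("rows cannot be treated as a table: ",
                                              conditionMessage(e)))
  }
  out <- rows
  if (!is.na(digits)) {
    num <- vapply(out, is.numeric, logical(1L))
    out[num] <- lapply(out[num], function(v) formatC(v, format = "f", digits = digits))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
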