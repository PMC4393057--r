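# Small in-code fixtures shared across test files.

tiny_matrix <- function(values, probes = NULL, samples = NULL, ...) {
  values <- as.matrix(values)
  if (is.null(probes)) probes <- sprintf("p%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values, probes, samples, ...)
}

# series-matrix text written to a temp file
write_series_lines <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

series_3x2 <- function(cell_21 = "0.5") {
  write_series_lines(c(
    "!Series_title\t\"toy\"",
    "!series_matrix_table_begin",
    "\"ID_REF\"\t\"GSM1\"\t\"GSM2\"",
    "A01\t1.5\t-0.25",
    paste0("B02\t", cell_21, "\t2"),
    "C03\t0\t3.75",
    "!series_matrix_table_end"))
}
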