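#' Construct an ExpressionMatrix
#'
#' An `ExpressionMatrix` is the package's container for a probe x sample table
#' of two-channel microarray log-ratio intensities (log of a common reference
#' channel against the sample channel, unitless). Missing cells are stored as
#' `NA`; probe identifiers are canonicalized to lower case so that set
#' operations between datasets are well defined (array probe IDs such as
#' "07I20"/"07l20" mix capital-I and lowercase-L spellings of the same probe).
#'
#' @param values numeric matrix, probes in rows and samples in columns.
#'   `NA` marks a missing measurement.
#' @param probe_ids character vector of probe identifiers, one per row.
#' @param sample_ids character vector of sample identifiers, one per column.
#' @param species_label free-text label for the dataset (e.g. a species name
#'   or GEO accession).
#' @param group_labels optional per-sample category (e.g. physiological state:
#'   summer, interbout arousal, late torpor). `NULL` or one entry per sample.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (numeric matrix with canonical `dimnames`), `species_label` and
#'   `group_labels`.
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2), c("p1", "p2", "p3"), c("s1", "s2"))
#' dim(m$values)
#' @export
expression_matrix <- function(values, probe_ids, sample_ids,
                              species_label = "", group_labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  probe_ids <- canonical_probe_id(as.character(probe_ids))
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(probe_ids))
    stop("number of rows (", nrow(values), ") does not match number of probe IDs (",
         length(probe_ids), ")")
  if (ncol(values) != length(sample_ids))
    stop("number of columns (", ncol(values), ") does not match number of sample IDs (",
         length(sample_ids), ")")
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup) > 0L)
    stop("duplicate probe ID(s) after canonicalization: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  if (!is.null(group_labels)) {
    group_labels <- as.character(group_labels)
    if (length(group_labels) != length(sample_ids))
      stop("group_labels must have one entry per sample (got ",
           length(group_labels), " for ", length(sample_ids), " samples)")
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(list(values = values,
                 species_label = as.character(species_label)[1L],
                 group_labels = group_labels),
            class = "ExpressionMatrix")
}

#' Canonicalize probe identifiers
#'
#' Lower-cases probe IDs and strips surrounding whitespace. Used on every
#' ingest path so that probe-set intersections across datasets are stable.
#'
#' @param ids character vector of probe identifiers.
#' @return character vector of canonical identifiers.
#' @export
canonical_probe_id <- function(ids) tolower(trimws(as.character(ids)))

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (nzchar(x$species_label)) x$species_label else "unlabelled"))
  n_na <- sum(is.na(x$values))
  cat(sprintf("  missing cells: %d (%.2f%%)\n", n_na,
              100 * n_na / max(1L, length(x$values))))
  if (!is.null(x$group_labels))
    cat("  groups:", paste(sprintf("%s=%d", names(table(x$group_labels)),
                                   table(x$group_labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Probe identifiers of an ExpressionMatrix
#' @param m an `ExpressionMatrix`.
#' @return character vector of canonical probe IDs, in row order.
#' @export
probe_ids <- function(m) rownames(m$values)

#' Sample identifiers of an ExpressionMatrix
#' @param m an `ExpressionMatrix`.
#' @return character vector of sample IDs, in column order.
#' @export
sample_ids <- function(m) colnames(m$values)

stopifnot_em <- function(m, arg = deparse(substitute(m))) {
  if (!inherits(m, "ExpressionMatrix"))
    stop(arg, " must be an ExpressionMatrix")
  invisible(m)
}
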