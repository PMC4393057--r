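#' Pooled mean over two datasets
#'
#' Arithmetic mean over all non-missing cells of both matrices pooled
#' together. This is the "assumed mean" of the cross-dataset Z-score
#' transform, computed over every sample of both datasets, and it appears as
#' a divisor in that transform, so a value of (or indistinguishable from)
#' zero is rejected rather than propagated.
#'
#' @param a,b two [expression_matrix()] objects.
#' @return The pooled mean, a single number.
#' @export
pooled_assumed_mean <- function(a, b) {
  stopifnot_em(a); stopifnot_em(b)
  cells <- c(a$values, b$values)
  cells <- cells[!is.na(cells)]
  if (length(cells) == 0L) stop("all cells missing: pooled mean undefined")
  mu <- mean(cells)
  spread <- if (length(cells) > 1L) stats::sd(cells) else 0
  # the transform divides by this mean: log-ratio data centred at 0 would
  # blow it up, so a mean within 5% of the data spread is rejected
  if (abs(mu) < max(1e-12, 0.05 * spread))
    stop("pooled mean is zero or near zero relative to the data spread ",
         "(degenerate): the cross-dataset transform divides by it; ",
         "shift the data by a reference offset first")
  mu
}

#' Whole-dataset standard deviation
#'
#' Sample standard deviation (divisor n - 1) over all non-missing cells of
#' one dataset, the per-dataset scale used by the cross-dataset Z-score
#' transform.
#'
#' @param m an [expression_matrix()].
#' @return A single positive number.
#' @export
dataset_sd <- function(m) {
  stopifnot_em(m)
  cells <- m$values[!is.na(m$values)]
  if (length(cells) < 2L)
    stop("need at least 2 non-missing cells to estimate a standard deviation")
  s <- stats::sd(cells)
  if (s == 0)
    stop("dataset standard deviation is zero (degenerate): all cells equal")
  s
}

#' Parameters of the cross-dataset Z-score transform
#'
#' Bundles the quantities the transform needs for one dataset: the pooled
#' ("assumed") mean over both datasets, this dataset's whole-matrix standard
#' deviation, and the per-sample column means of this dataset.
#'
#' @param m the dataset to be transformed.
#' @param mu_assumed pooled mean from [pooled_assumed_mean()].
#' @return A list of class `z_params` with elements `mu_assumed`,
#'   `sd_dataset` and `mu_initial` (named per-sample means).
#' @export
z_params <- function(m, mu_assumed) {
  stopifnot_em(m)
  if (!is.numeric(mu_assumed) || length(mu_assumed) != 1L || is.na(mu_assumed))
    stop("mu_assumed must be a single number")
  if (abs(mu_assumed) < 1e-12) stop("mu_assumed is zero (degenerate)")
  structure(list(mu_assumed = mu_assumed,
                 sd_dataset = dataset_sd(m),
                 mu_initial = colMeans(m$values, na.rm = TRUE)),
            class = "z_params")
}

#' Cross-dataset Z-score transform
#'
#' Makes probe scores comparable across two datasets measured on the same
#' platform. With `formula = "scaled"` (the default) each non-missing cell
#' `v` in sample `s` becomes
#'
#' \deqn{z = | (v \cdot \mu_s / \mu_A - \mu_A) / SD |}
#'
#' where `mu_s` is the per-sample mean of the dataset being transformed,
#' `mu_A` the pooled mean over both datasets, and `SD` the whole-matrix
#' standard deviation of this dataset. The per-sample rescaling by
#' `mu_s / mu_A` aligns sample levels to the pooled level before centring;
#' absolute values are taken, so downstream variation statistics act on
#' magnitudes of deviation. `formula = "conventional"` instead applies the
#' ordinary dataset z-score `|(v - mean) / sd|` (whole-matrix mean and sd),
#' as a sanity-check alternative; note the scaled form is the package
#' default because it is what the cross-dataset screening procedure is
#' defined on.
#'
#' Missing cells stay missing; no imputation is done.
#'
#' @param m an [expression_matrix()].
#' @param params a [z_params()] object for `m` (required for `"scaled"`).
#' @param formula `"scaled"` or `"conventional"`.
#' @return A list of class `z_matrix`: `values` (probe x sample matrix of
#'   absolute scores, all `>= 0`), `params`, `formula` and `lineage` (the
#'   source dataset's label). Row/column names follow `m`.
#' @export
z_transform <- function(m, params = NULL, formula = c("scaled", "conventional")) {
  stopifnot_em(m)
  formula <- match.arg(formula)
  v <- m$values
  if (formula == "scaled") {
    if (!inherits(params, "z_params"))
      stop("params must be a z_params object for the scaled formula")
    if (length(params$mu_initial) != ncol(v))
      stop("params carry ", length(params$mu_initial), " per-sample means for a ",
           ncol(v), "-sample matrix")
    scale_s <- params$mu_initial / params$mu_assumed
    z <- abs((sweep(v, 2L, scale_s, `*`) - params$mu_assumed) / params$sd_dataset)
  } else {
    mu <- mean(v, na.rm = TRUE)
    s <- dataset_sd(m)
    z <- abs((v - mu) / s)
    params <- structure(list(mu_assumed = mu, sd_dataset = s,
                             mu_initial = colMeans(v, na.rm = TRUE)),
                        class = "z_params")
  }
  structure(list(values = z, params = params, formula = formula,
                 lineage = m$species_label, group_labels = m$group_labels),
            class = "z_matrix")
}

#' @export
print.z_matrix <- function(x, ...) {
  cat(sprintf("z_matrix (%s formula): %d probes x %d samples, source '%s'\n",
              x$formula, nrow(x$values), ncol(x$values), x$lineage))
  cat(sprintf("  mu_assumed = %.6g, sd_dataset = %.6g\n",
              x$params$mu_assumed, x$params$sd_dataset))
  invisible(x)
}
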