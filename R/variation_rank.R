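#' Per-probe coefficient of variation
#'
#' For each probe, the coefficient of variation (CV) of its absolute
#' normalized scores across samples: sample standard deviation (divisor
#' n - 1) divided by the arithmetic mean, over non-missing values only.
#' Probes with fewer than `min_samples` non-missing values, or with a mean of
#' exactly zero (the quotient is undefined), are excluded; exclusions are
#' recorded in the result's `"excluded"` attribute, never dropped silently.
#'
#' @param z a `z_matrix` from [z_transform()], or any numeric matrix with
#'   probe rownames.
#' @param min_samples minimum non-missing values a probe needs (default 3).
#' @return A data.frame of class `cv_table` with columns `probe_id`, `cv`,
#'   `n_used`, and (after [rank_ascending()]) `rank`. Attribute `excluded` is
#'   a data.frame of `(probe_id, reason)`.
#' @export
probe_cv <- function(z, min_samples = 3L) {
  v <- as_values(z)
  n_used <- rowSums(!is.na(v))
  mu <- rowMeans(v, na.rm = TRUE)
  sd_ <- apply(v, 1L, stats::sd, na.rm = TRUE)
  too_few <- n_used < min_samples
  zero_mean <- !too_few & mu == 0
  keep <- !too_few & !zero_mean
  excluded <- data.frame(
    probe_id = c(rownames(v)[too_few], rownames(v)[zero_mean]),
    reason = c(rep("too-few-samples", sum(too_few)),
               rep("zero-mean", sum(zero_mean))),
    stringsAsFactors = FALSE)
  out <- data.frame(probe_id = rownames(v)[keep],
                    cv = (sd_ / mu)[keep],
                    n_used = n_used[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("cv_table", "data.frame")
  out
}

as_values <- function(z) {
  v <- if (inherits(z, "z_matrix") || inherits(z, "ExpressionMatrix")) z$values
       else as.matrix(z)
  if (is.null(rownames(v))) rownames(v) <- sprintf("p%05d", seq_len(nrow(v)))
  v
}

#' Rank probes by ascending CV
#'
#' Adds ascending ranks (1 = smallest CV, i.e. most invariant) with average
#' ranks on ties, so the ranks always sum to N(N+1)/2.
#'
#' @param t a `cv_table` from [probe_cv()].
#' @return The same table with a `rank` column.
#' @export
rank_ascending <- function(t) {
  if (!"cv" %in% names(t)) stop("table has no 'cv' column")
  t$rank <- rank(t$cv, ties.method = "average")
  t
}

#' Rank difference between two datasets
#'
#' Signed per-probe difference `rank_a - rank_b` for two CV tables over the
#' same probe universe.
#'
#' @param a,b ranked `cv_table`s ([rank_ascending()] applied).
#' @return data.frame `(probe_id, rank_diff)` in `a`'s probe order.
#' @export
rank_difference <- function(a, b) {
  for (t in list(a, b)) if (!"rank" %in% names(t))
    stop("both tables must be ranked (call rank_ascending first)")
  only_a <- setdiff(a$probe_id, b$probe_id)
  only_b <- setdiff(b$probe_id, a$probe_id)
  if (length(only_a) > 0L || length(only_b) > 0L)
    stop("probe universes differ; symmetric difference: ",
         paste(utils::head(c(only_a, only_b), 10L), collapse = ", "))
  data.frame(probe_id = a$probe_id,
             rank_diff = a$rank - b$rank[match(a$probe_id, b$probe_id)],
             stringsAsFactors = FALSE)
}

#' Select the lowest-CV decile
#'
#' The `round_half_away(fraction * N)` probes with the smallest CV rank
#' (e.g. 1258 of 12575 probes at the default fraction 0.1, rounding half
#' away from zero). Ties at the selection boundary are broken by probe-ID
#' lexicographic order, so the set is deterministic.
#'
#' @param t a ranked `cv_table`.
#' @param fraction fraction of probes to keep, in `(0, 1]`.
#' @param label optional source-dataset label carried on the set.
#' @return A list of class `decile_set`: `probe_ids` (sorted), `label`,
#'   `fraction`, `n_universe`.
#' @export
lowest_decile <- function(t, fraction = 0.1, label = "") {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      is.na(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be a single number in (0, 1]")
  if (!"rank" %in% names(t)) t <- rank_ascending(t)
  k <- round_half_away(fraction * nrow(t))
  ord <- order(t$rank, t$probe_id)
  structure(list(probe_ids = sort(t$probe_id[ord[seq_len(k)]]),
                 label = label, fraction = fraction, n_universe = nrow(t)),
            class = "decile_set")
}

#' Round half away from zero
#'
#' Commercial rounding: `round_half_away(1257.5) == 1258`, unlike base R's
#' round-half-to-even. Used for decile sizes.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @export
round_half_away <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' Overlap of two decile sets
#'
#' Intersection of two probe sets, with the overlap percentage computed
#' against the size of the first set (the fixed decile size), matching the
#' convention `100 * |A intersect B| / |A|`.
#'
#' @param a,b `decile_set`s over the same probe universe.
#' @return A list `(probe_ids, count, percent)`.
#' @export
decile_overlap <- function(a, b) {
  ids_a <- as_probe_set(a); ids_b <- as_probe_set(b)
  if (length(ids_a) != length(ids_b))
    warning("decile sets differ in size (", length(ids_a), " vs ",
            length(ids_b), "); percent uses the first set's size")
  common <- sort(intersect(ids_a, ids_b))
  list(probe_ids = common, count = length(common),
       percent = 100 * length(common) / length(ids_a))
}

as_probe_set <- function(x) {
  if (inherits(x, "decile_set")) x$probe_ids else as.character(x)
}

#' Spearman correlation with a Fisher-z significance test
#'
#' Spearman's rho (Pearson correlation of average-tie ranks) with the
#' classical z-test for a correlation coefficient: `z = atanh(rho) *
#' sqrt(n - 3)` under the null of no correlation, two-sided normal p-value.
#' The p-value is computed on the log scale internally so extreme
#' correlations at large n report magnitudes like 1e-56 instead of
#' underflowing to zero.
#'
#' @param x,y paired numeric vectors; pairs with a missing side are dropped.
#' @return A list `(rho, z, p_two_sided, n)`.
#' @export
spearman_with_ztest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be the same length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs (got ", n, ")")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: one input is constant")
  rho <- stats::cor(rank(x, ties.method = "average"),
                    rank(y, ties.method = "average"))
  ft <- fisher_z_test(rho, n)
  list(rho = rho, z = ft$z, p_two_sided = ft$p_two_sided, n = n)
}

#' Fisher z-test for a correlation coefficient
#'
#' Tests a correlation coefficient against the null of no correlation using
#' the Fisher transform: `z = atanh(rho) * sqrt(n - 3)` is approximately
#' standard normal under the null; the p-value is the two-sided normal tail.
#'
#' @param rho correlation coefficient in `[-1, 1]`.
#' @param n number of paired observations (>= 4).
#' @return A list `(z, p_two_sided)`. `|rho| = 1` reports `z = +/-Inf`,
#'   `p = 0`.
#' @export
fisher_z_test <- function(rho, n) {
  if (!is.numeric(rho) || abs(rho) > 1) stop("rho must lie in [-1, 1]")
  if (n < 4L) stop("need n >= 4")
  if (abs(rho) == 1) return(list(z = sign(rho) * Inf, p_two_sided = 0))
  z <- atanh(rho) * sqrt(n - 3)
  list(z = z, p_two_sided = 2 * stats::pnorm(-abs(z)))
}
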