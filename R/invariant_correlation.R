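#' Select the k most stable probes
#'
#' The k probes with the lowest stability index (deterministic tie-break by
#' probe ID via [rank_stability()]).
#'
#' @param t a `stability_table`.
#' @param k how many probes (default 10).
#' @return Character vector of k probe IDs, in rank order.
#' @export
select_top_invariant <- function(t, k = 10L) {
  k <- as.integer(k)
  if (k < 1L || k > nrow(t)) stop("k must lie in [1, ", nrow(t), "]")
  if (!"rank" %in% names(t)) t <- rank_stability(t)
  t$probe_id[order(t$rank)][seq_len(k)]
}

#' Random probe selection with exclusions
#'
#' Draws k distinct probes uniformly without replacement from
#' `universe \ exclude`, reproducibly for a given seed. Used to build the
#' "Random-10" comparison sets.
#'
#' @param universe character vector of candidate probe IDs.
#' @param exclude probe IDs that may not be selected.
#' @param k number of probes (default 10).
#' @param seed integer seed.
#' @return Character vector of k probe IDs.
#' @export
select_random_excluding <- function(universe, exclude = character(0),
                                    k = 10L, seed = 1L) {
  pool <- setdiff(unique(as_probe_set(universe)), as_probe_set(exclude))
  k <- as.integer(k)
  if (k < 1L) stop("k must be positive")
  if (length(pool) < k)
    stop("only ", length(pool), " candidates remain after exclusions; need ", k)
  set.seed(seed)
  sample(pool, k)
}

#' Pairwise squared Pearson correlations between two probe lists
#'
#' For every pair (a, b) with `a` in `probes_a` and `b` in `probes_b`,
#' computes the coefficient of determination r^2 of the two probes'
#' expression profiles across samples. Correlations are pairwise-complete;
#' pairs with fewer than `min_pairs` complete observations or with a constant
#' profile are excluded and counted in the `"n_excluded"` attribute.
#'
#' @param m expression table (matrix, `ExpressionMatrix`, or `z_matrix`).
#' @param probes_a,probes_b disjoint probe ID vectors.
#' @param min_pairs minimum complete observations per pair (default 3).
#' @return Numeric vector of r^2 values (length `|a| * |b|` minus
#'   exclusions), all in `[0, 1]`, with attributes `n_pairs` and
#'   `n_excluded`.
#' @export
pairwise_r2 <- function(m, probes_a, probes_b, min_pairs = 3L) {
  v <- as_values(m)
  probes_a <- canonical_probe_id(as_probe_set(probes_a))
  probes_b <- canonical_probe_id(as_probe_set(probes_b))
  if (length(intersect(probes_a, probes_b)) > 0L)
    stop("probe lists must be disjoint; shared: ",
         paste(utils::head(intersect(probes_a, probes_b), 5L), collapse = ", "))
  va <- t(restrict_probes(v, probes_a))
  vb <- t(restrict_probes(v, probes_b))
  suppressWarnings(
    r <- stats::cor(va, vb, use = "pairwise.complete.obs"))
  n_ok <- crossprod(!is.na(va), !is.na(vb))
  r[n_ok < min_pairs] <- NA_real_
  r2 <- as.vector(r^2)
  excluded <- sum(is.na(r2))
  out <- r2[!is.na(r2)]
  attr(out, "n_pairs") <- length(out)
  attr(out, "n_excluded") <- excluded
  out
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test (Welch-Satterthwaite degrees of freedom) comparing
#' the means of two samples, as used to compare the r^2 of invariant probes
#' against the r^2 of randomly selected probes.
#'
#' @param s1,s2 numeric vectors (each >= 2 values; not both constant).
#' @return A list `(t, df, p_two_sided, mean1, mean2, n1, n2)`.
#' @export
welch_ttest <- function(s1, s2) {
  s1 <- s1[!is.na(s1)]; s2 <- s2[!is.na(s2)]
  if (length(s1) < 2L || length(s2) < 2L)
    stop("both samples need at least 2 values")
  if (stats::var(s1) == 0 && stats::var(s2) == 0)
    stop("both samples have zero variance: test undefined")
  ht <- stats::t.test(s1, s2, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_two_sided = ht$p.value,
       mean1 = mean(s1), mean2 = mean(s2),
       n1 = length(s1), n2 = length(s2))
}

#' Numerical error of self-correlation
#'
#' Correlates every probe's profile with itself and reports the distribution
#' of `1 - r`. In exact arithmetic every error is 0; the observed mean and sd
#' estimate the floating-point error floor of the correlation machinery on
#' this data, an empirical anchor for interpreting tiny r^2 differences.
#'
#' @param m expression table.
#' @param min_samples minimum non-missing values a probe needs (default 3).
#' @return A list `(mean_error, sd_error, max_abs_error, errors, n_excluded)`;
#'   `errors` is the per-probe `1 - r` vector.
#' @export
self_correlation_error <- function(m, min_samples = 3L) {
  v <- as_values(m)
  n_used <- rowSums(!is.na(v))
  sd_ <- apply(v, 1L, stats::sd, na.rm = TRUE)
  keep <- n_used >= min_samples & !is.na(sd_) & sd_ > 0
  vk <- v[keep, , drop = FALSE]
  err <- vapply(seq_len(nrow(vk)), function(i) {
    x <- vk[i, ]; x <- x[!is.na(x)]
    1 - stats::cor(x, x)
  }, numeric(1L))
  list(mean_error = mean(err), sd_error = stats::sd(err),
       max_abs_error = max(abs(err)), errors = err,
       n_excluded = sum(!keep))
}

#' Compare transcriptome correlation of invariant vs random probes
#'
#' End-to-end test of the hypothesis that invariant probes are less
#' correlated with the rest of the transcriptome than randomly chosen
#' probes. Given a ranked stability table for one dataset, takes the
#' `k` most stable probes ("NF-k"), draws `n_replicates` random probe sets of
#' the same size from the remaining probes, and for each set computes the
#' pairwise r^2 against "others" (all probes not in NF-k nor in the current
#' random set). A Welch test compares the NF-k r^2 sample against the pooled
#' random-replicate r^2 values; per-replicate tests are also returned.
#'
#' @param m expression table for the dataset.
#' @param stability ranked `stability_table` for (a candidate subset of) `m`.
#' @param k size of the invariant and random sets (default 10).
#' @param n_replicates number of random sets (default 5).
#' @param seed integer seed; replicate r uses seed + r.
#' @return A list of class `correlation_report`: `nf_probes`,
#'   `random_probes` (list of replicates), `n_others`, `nf_r2` summary
#'   `(n_pairs, mean, sd)`, `random_r2` per-replicate summary data.frame,
#'   `welch` (pooled test), `welch_per_replicate`, `self_error`, `seed`.
#' @export
correlation_report <- function(m, stability, k = 10L, n_replicates = 5L,
                               seed = 1L) {
  v <- as_values(m)
  universe <- rownames(v)
  nf <- select_top_invariant(stability, k)
  nf_sets <- lapply(seq_len(n_replicates), function(r)
    select_random_excluding(universe, nf, k, seed = seed + r))
  r2_nf <- NULL
  rep_rows <- vector("list", n_replicates)
  r2_rand_all <- vector("list", n_replicates)
  welch_rep <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rand <- nf_sets[[r]]
    others <- setdiff(universe, c(nf, rand))
    if (is.null(r2_nf)) r2_nf <- pairwise_r2(v, nf, others)
    r2_rand <- pairwise_r2(v, rand, others)
    r2_rand_all[[r]] <- as.numeric(r2_rand)
    rep_rows[[r]] <- data.frame(replicate = r,
                                n_pairs = attr(r2_rand, "n_pairs"),
                                mean_r2 = mean(r2_rand),
                                sd_r2 = stats::sd(r2_rand))
    welch_rep[[r]] <- welch_ttest(r2_nf, r2_rand)
  }
  pooled <- unlist(r2_rand_all)
  structure(list(
    nf_probes = nf,
    random_probes = nf_sets,
    n_others = length(setdiff(universe, nf)) - k,
    nf_r2 = list(n_pairs = attr(r2_nf, "n_pairs"),
                 mean = mean(r2_nf), sd = stats::sd(r2_nf)),
    random_r2 = do.call(rbind, rep_rows),
    welch = welch_ttest(r2_nf, pooled),
    welch_per_replicate = welch_rep,
    self_error = self_correlation_error(v),
    seed = seed), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Invariant-vs-random correlation report (%d invariant probes, %d others)\n",
              length(x$nf_probes), x$n_others))
  cat(sprintf("  r2 invariant: mean %.3f (sd %.3f, %d pairs)\n",
              x$nf_r2$mean, x$nf_r2$sd, x$nf_r2$n_pairs))
  cat(sprintf("  r2 random:    mean %.3f-%.3f over %d replicates\n",
              min(x$random_r2$mean_r2), max(x$random_r2$mean_r2),
              nrow(x$random_r2)))
  cat(sprintf("  Welch (pooled): t = %.2f, df = %.0f, p = %.3g\n",
              x$welch$t, x$welch$df, x$welch$p_two_sided))
  invisible(x)
}
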