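#' Model-based expression stability index
#'
#' Implements the variance-decomposition stability model of the NormFinder
#' family (Andersen-style): each candidate probe is scored by combining its
#' intragroup variation with its (shrunken) intergroup deviation, so that a
#' low index means a probe that is both quiet within groups and unmoved
#' between groups -- the profile of a good reference gene.
#'
#' For probe i in group g with n_g samples and k candidate probes, the model
#' is `y_igj = probe effect + sample effect + noise(0, sigma2_ig)`. The
#' within-group variance `sigma2_ig` is estimated from the two-way residuals
#' `r_igj = y_igj - ybar_ig. - ybar_.gj + ybar_.g.`:
#'
#' \deqn{\hat\sigma^2_{ig} = \frac{k}{k-2}\Big(s^2_{ig} -
#'   \frac{\bar{s}^2_{g}}{k-1}\Big), \quad s^2_{ig} = \frac{\sum_j
#'   r_{igj}^2}{n_g - 1}}
#'
#' (truncated at 0), the unbiased correction accounting for the candidate
#' average entering the residuals. The intergroup deviation `d_ig` is the
#' doubly centred matrix of probe-by-group means (per probe the `d_ig` sum to
#' zero across groups). Because each `d_ig` is estimated with sampling
#' variance about `sigma2_ig / n_g`, it is shrunk toward 0 by the ratio of
#' the between-probe variance of d,
#' `gamma2 = max(0, sum(d^2) / ((k-1)(G-1)) - mean(sigma2_ig / n_g))`,
#' to `gamma2 + sigma2_ig / n_g`. The stability index of probe i averages,
#' over groups, the absolute shrunken deviation plus the sampling spread of
#' the deviation estimate:
#'
#' \deqn{\rho_i = \frac{1}{G} \sum_g \Big( |\tilde d_{ig}| +
#'   \sqrt{\hat\sigma^2_{ig}/n_g} \Big)}
#'
#' Lower is more stable. (The spread term is the standard error of `d_ig`
#' rather than its posterior standard deviation `sqrt(gamma2 v / (gamma2 +
#' v))`; the two coincide when between-group variation dominates, but the
#' standard error keeps the index ordered by intragroup variance when
#' `gamma2` shrinks to zero, where the posterior form collapses to 0 for
#' every probe.) Missing cells are handled pairwise-complete (group
#' means and residual sums use the observed cells; `n_g` becomes the probe's
#' observed count in that group) and counted in the `"n_missing"` attribute.
#'
#' @param m expression table: a `z_matrix`, [expression_matrix()], or numeric
#'   matrix with probe rownames (probes x samples).
#' @param groups per-sample group labels (length = number of samples). At
#'   least 2 groups with at least 2 samples each.
#' @param probes optional candidate probe list; stability is estimated within
#'   this list only (the candidate set defines the "overall variation"
#'   context). Default: all probes of `m`. At least 3 probes.
#' @param label label stored on the result (e.g. the candidate-list name).
#' @return A `stability_table`: data.frame `(probe_id, stability, rank)`
#'   ranked by [rank_stability()], with attributes `mode`, `label`,
#'   `n_missing`, and `excluded` (probes dropped for having fewer than 2
#'   observations in some group).
#' @seealso [stability_ungrouped()] for the single-group degenerate case,
#'   [rank_stability()], [top_k_overlap()].
#' @export
stability_grouped <- function(m, groups, probes = NULL, label = "") {
  v <- as_values(m)
  if (missing(groups) || is.null(groups)) {
    groups <- if (!is.null(m$group_labels)) m$group_labels else
      stop("groups must be supplied (none stored on the input)")
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(v))
    stop("groups has length ", length(groups), " for ", ncol(v), " samples")
  v <- restrict_probes(v, probes)
  glev <- unique(groups)
  G <- length(glev)
  if (G < 2L) stop("need at least 2 groups; use stability_ungrouped otherwise")
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("every group needs at least 2 samples; offending group(s): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  k <- nrow(v)
  if (k < 3L) stop("the grouped model needs at least 3 candidate probes")

  # drop probes unobservable in some group (would make d_ig undefined)
  obs_by_group <- sapply(glev, function(g)
    rowSums(!is.na(v[, groups == g, drop = FALSE])))
  bad <- rowSums(obs_by_group < 2L) > 0L
  excluded <- rownames(v)[bad]
  if (all(bad)) stop("no probe has >= 2 observations in every group")
  v <- v[!bad, , drop = FALSE]
  obs_by_group <- obs_by_group[!bad, , drop = FALSE]
  k <- nrow(v)
  if (k < 3L) stop("fewer than 3 probes remain after missing-data exclusions")
  n_missing <- sum(is.na(v))

  sigma2 <- matrix(NA_real_, k, G, dimnames = list(rownames(v), glev))
  zmeans <- matrix(NA_real_, k, G, dimnames = list(rownames(v), glev))
  for (gi in seq_len(G)) {
    y <- v[, groups == glev[gi], drop = FALSE]
    probe_mean <- rowMeans(y, na.rm = TRUE)
    sample_mean <- colMeans(y, na.rm = TRUE)
    grand <- mean(y, na.rm = TRUE)
    r <- y - probe_mean - rep(sample_mean, each = k) + grand
    n_i <- obs_by_group[, gi]
    s2 <- rowSums(r^2, na.rm = TRUE) / (n_i - 1)
    sigma2[, gi] <- pmax(k / (k - 2) * (s2 - mean(s2) / (k - 1)), 0)
    zmeans[, gi] <- probe_mean
  }
  d <- zmeans - rowMeans(zmeans) - rep(colMeans(zmeans), each = k) + mean(zmeans)
  vard <- sigma2 / obs_by_group
  gamma2 <- max(0, sum(d^2) / ((k - 1) * (G - 1)) - mean(vard))
  shrink <- gamma2 / (gamma2 + vard)
  shrink[!is.finite(shrink)] <- 0  # gamma2 = 0 and vard = 0: no deviation at all
  d_tilde <- d * shrink
  spread <- sqrt(vard)
  stability <- rowMeans(abs(d_tilde) + spread)

  out <- rank_stability(new_stability_table(rownames(v), stability,
                                            mode = "grouped", label = label))
  attr(out, "n_missing") <- n_missing
  attr(out, "excluded") <- excluded
  out
}

#' Stability index without group structure
#'
#' The single-group degenerate case of the stability model: with no groups
#' there is no intergroup deviation, and a probe's stability index reduces to
#' the sample standard deviation of its values across samples (divisor
#' n - 1, non-missing values only). Probes with fewer than 2 observations are
#' excluded and listed in the `"excluded"` attribute.
#'
#' @inheritParams stability_grouped
#' @return A ranked `stability_table` (see [stability_grouped()]), with
#'   attribute `mode = "ungrouped"`.
#' @export
stability_ungrouped <- function(m, probes = NULL, label = "") {
  v <- as_values(m)
  v <- restrict_probes(v, probes)
  if (ncol(v) < 2L) stop("need at least 2 samples")
  n_used <- rowSums(!is.na(v))
  bad <- n_used < 2L
  sd_ <- apply(v[!bad, , drop = FALSE], 1L, stats::sd, na.rm = TRUE)
  out <- rank_stability(new_stability_table(rownames(v)[!bad], sd_,
                                            mode = "ungrouped", label = label))
  attr(out, "excluded") <- rownames(v)[bad]
  out
}

restrict_probes <- function(v, probes) {
  if (is.null(probes)) return(v)
  probes <- canonical_probe_id(as_probe_set(probes))
  if (length(probes) == 0L) stop("probe list is empty")
  miss <- setdiff(probes, rownames(v))
  if (length(miss) > 0L)
    stop("probe(s) not in the expression table: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  v[probes, , drop = FALSE]
}

new_stability_table <- function(probe_id, stability, mode, label) {
  out <- data.frame(probe_id = probe_id, stability = unname(stability),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "label") <- label
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Rank a stability table
#'
#' Ascending ranks on the stability index (rank 1 = most stable), ties broken
#' lexicographically by probe ID so rankings are deterministic. Rows are
#' reordered by rank; ranks are exactly `1..N`.
#'
#' @param t a `stability_table`.
#' @return The table sorted by rank, with a `rank` column.
#' @export
rank_stability <- function(t) {
  if (!"stability" %in% names(t)) stop("table has no 'stability' column")
  ord <- order(t$stability, t$probe_id)
  t <- t[ord, , drop = FALSE]
  t$rank <- seq_len(nrow(t))
  rownames(t) <- NULL
  t
}

#' Overlap of the top-k most stable probes of two tables
#'
#' Intersects the k lowest-stability probes of each table; used to ask
#' whether two candidate rankings nominate the same reference probes.
#'
#' @param a,b ranked `stability_table`s.
#' @param k how many top probes of each table to compare (default 20).
#' @return A list `(probe_ids, count)`.
#' @export
top_k_overlap <- function(a, b, k = 20L) {
  k <- as.integer(k)
  if (k < 1L || k > min(nrow(a), nrow(b)))
    stop("k must lie in [1, ", min(nrow(a), nrow(b)), "]")
  top <- function(t) {
    if (!"rank" %in% names(t)) t <- rank_stability(t)
    t$probe_id[t$rank <= k]
  }
  ids <- sort(intersect(top(a), top(b)))
  list(probe_ids = ids, count = length(ids))
}
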