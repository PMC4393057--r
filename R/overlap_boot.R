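#' Bootstrap null distribution for a probe-list overlap
#'
#' Builds an empirical null for the "percentage of probes common to two
#' candidate lists" statistic. Each replicate draws two with-replacement
#' samples, of sizes `|set_a|` and `|set_b|`, from a resampling universe,
#' deduplicates each sample, and records `100 * |intersection| / |set_a|`
#' (the denominator is the fixed size of the first list, matching how the
#' observed statistic is computed).
#'
#' The universe is chosen by `scheme`:
#' \describe{
#'   \item{`"union"`}{(default) the union of the two candidate lists --
#'     resampling "from the lists themselves";}
#'   \item{`"universe"`}{the full probe universe (`universe` must be given),
#'     the null of two independently drawn lists;}
#'   \item{`"per-set"`}{each resample is drawn from its own list.}
#' }
#'
#' @param set_a,set_b `decile_set`s or character vectors of probe IDs.
#' @param n_boot number of replicates (>= 1; default 2000).
#' @param scheme resampling universe, see Details.
#' @param seed integer seed; the sequence is reproducible given the seed.
#' @param universe full probe universe (required for `scheme = "universe"`).
#' @return Numeric vector of `n_boot` overlap percentages, with attributes
#'   `scheme` and `seed`.
#' @export
bootstrap_null <- function(set_a, set_b, n_boot = 2000L,
                           scheme = c("union", "universe", "per-set"),
                           seed = 1L, universe = NULL) {
  scheme <- match.arg(scheme)
  ids_a <- as_probe_set(set_a); ids_b <- as_probe_set(set_b)
  if (length(ids_a) == 0L || length(ids_b) == 0L)
    stop("candidate sets must be non-empty")
  n_boot <- as.integer(n_boot)
  if (is.na(n_boot) || n_boot < 1L) stop("n_boot must be at least 1")
  pool_a <- switch(scheme,
    "union" = union(ids_a, ids_b),
    "universe" = {
      if (is.null(universe)) stop("scheme 'universe' needs the probe universe")
      unique(as_probe_set(universe))
    },
    "per-set" = ids_a)
  pool_b <- if (scheme == "per-set") ids_b else pool_a
  set.seed(seed)
  pct <- vapply(seq_len(n_boot), function(i) {
    ra <- unique(sample(pool_a, length(ids_a), replace = TRUE))
    rb <- unique(sample(pool_b, length(ids_b), replace = TRUE))
    100 * length(intersect(ra, rb)) / length(ids_a)
  }, numeric(1L))
  attr(pct, "scheme") <- scheme
  attr(pct, "seed") <- seed
  pct
}

#' Z-test of an observed overlap against its bootstrap null
#'
#' Standardizes the observed overlap percentage by the mean and standard
#' deviation of the bootstrap distribution and reports a two-sided normal
#' p-value. P-values below the smallest representable double are reported as
#' 0 in `p_two_sided` with the printable string `"< 1e-300"` in `p_label`.
#'
#' @param observed_pct the observed overlap percentage.
#' @param null_pcts replicate percentages from [bootstrap_null()].
#' @param observed_count optional raw intersection count, echoed in the result.
#' @return A list of class `overlap_test`: `observed_count`, `observed_pct`,
#'   `boot_mean_pct`, `boot_sd_pct`, `z`, `p_two_sided`, `p_label`, `n_boot`,
#'   `scheme`, `seed`.
#' @export
overlap_ztest <- function(observed_pct, null_pcts, observed_count = NA_integer_) {
  m <- mean(null_pcts)
  s <- stats::sd(null_pcts)
  if (!is.finite(s) || s == 0)
    stop("bootstrap null has zero spread: z-test degenerate")
  z <- (observed_pct - m) / s
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(observed_count = observed_count,
                 observed_pct = observed_pct,
                 boot_mean_pct = m,
                 boot_sd_pct = s,
                 z = z,
                 p_two_sided = p,
                 p_label = if (p < 1e-300) "< 1e-300" else
                   formatC(p, format = "e", digits = 2),
                 n_boot = length(null_pcts),
                 scheme = attr(null_pcts, "scheme"),
                 seed = attr(null_pcts, "seed")),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("Overlap test: observed %.2f%% vs bootstrap %.2f%% (sd %.2f%%), n_boot = %d\n",
              x$observed_pct, x$boot_mean_pct, x$boot_sd_pct, x$n_boot))
  cat(sprintf("  z = %.2f, two-sided p %s\n", x$z,
              if (startsWith(x$p_label, "<")) x$p_label else paste("=", x$p_label)))
  invisible(x)
}
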