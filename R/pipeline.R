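#' Default pipeline configuration
#'
#' Flat key/value configuration for [run_pipeline()]. Keys use dotted
#' section names and can be read from / written to a plain-text file with
#' one `key: value` per line ([read_pipeline_config()]). All seeds are
#' explicit -- the pipeline never seeds from the clock.
#'
#' @return Named list of defaults:
#' \describe{
#'   \item{`input.a`, `input.b`}{paths to two series-matrix files; empty
#'     means "simulate instead" using the `simulate.*` keys.}
#'   \item{`simulate.*`}{[sim_config()] fields (`simulate.n_probes`,
#'     `simulate.share_kappa`, `simulate.seed`, ...).}
#'   \item{`normalization.formula`}{`scaled` (cross-dataset formula, default)
#'     or `conventional`.}
#'   \item{`cv.fraction`}{decile fraction (default 0.1).}
#'   \item{`cv.min_samples`}{minimum non-missing values per probe.}
#'   \item{`normfinder.mode`}{`grouped`, `ungrouped`, or `auto` (grouped when
#'     group labels exist).}
#'   \item{`normfinder.k_top`}{top-list size for overlap counts (default 20).}
#'   \item{`normfinder.all_probes`}{also rank the full probe universe
#'     (`true`/`false`).}
#'   \item{`bootstrap.n`, `bootstrap.scheme`, `bootstrap.seed`}{overlap-null
#'     settings (2000, `union`, 101).}
#'   \item{`correlation.k`, `correlation.replicates`, `correlation.seed`}{
#'     invariant-correlation settings (10, 5, 202).}
#' }
#' @export
default_pipeline_config <- function() {
  c(list(input.a = "", input.b = "",
         normalization.formula = "scaled",
         cv.fraction = 0.1, cv.min_samples = 3L,
         normfinder.mode = "auto", normfinder.k_top = 20L,
         normfinder.all_probes = FALSE,
         bootstrap.n = 2000L, bootstrap.scheme = "union", bootstrap.seed = 101L,
         correlation.k = 10L, correlation.replicates = 5L,
         correlation.seed = 202L),
    stats::setNames(unclass(sim_config()),
                    paste0("simulate.", names(unclass(sim_config())))))
}

#' Read a pipeline configuration file
#'
#' Plain-text `key: value` lines (`=` also accepted); `#` starts a comment;
#' unknown keys are rejected so typos fail loudly. Values are coerced to the
#' type of the default for that key.
#'
#' @param path config file path.
#' @return Full config list (defaults overridden by the file).
#' @export
read_pipeline_config <- function(path) {
  cfg <- default_pipeline_config()
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9._]+)\\s*[:=]\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("cannot parse config line: '", ln, "'")
    key <- m[2L]; val <- trimws(m[3L])
    if (!key %in% names(cfg)) stop("unknown config key: '", key, "'")
    cfg[[key]] <- coerce_like(val, cfg[[key]], key)
  }
  cfg
}

coerce_like <- function(val, template, key) {
  if (is.logical(template)) {
    out <- tolower(val) %in% c("true", "yes", "1")
    if (!tolower(val) %in% c("true", "yes", "1", "false", "no", "0"))
      stop("config key '", key, "' expects a logical, got '", val, "'")
    out
  } else if (is.integer(template)) {
    out <- suppressWarnings(as.integer(val))
    if (is.na(out)) stop("config key '", key, "' expects an integer, got '", val, "'")
    out
  } else if (is.numeric(template)) {
    out <- suppressWarnings(as.numeric(val))
    if (is.na(out)) stop("config key '", key, "' expects a number, got '", val, "'")
    out
  } else as.character(val)
}

#' Write a pipeline configuration file
#'
#' @param cfg config list (as from [default_pipeline_config()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  fmt <- vapply(cfg, function(v)
    if (is.logical(v)) tolower(as.character(v)) else as.character(v),
    character(1L))
  writeLines(paste0(names(cfg), ": ", fmt), path)
  invisible(path)
}

#' Run the full reference-gene stability pipeline
#'
#' Executes the whole screening workflow on two datasets (read from
#' series-matrix files, simulated from the `simulate.*` config, or passed
#' directly): cross-dataset Z-normalization; per-probe CV, ascending ranks
#' and rank differences; lowest-decile selection in each dataset and their
#' overlap; Spearman/Fisher-z correlation of the CV values across datasets;
#' stability-index rankings of each decile and of the common list under both
#' datasets (four tables, plus optional all-probe rankings); top-k overlap
#' counts between own-decile and common-list rankings; a bootstrap z-test of
#' the decile overlap; and the invariant-vs-random transcriptome correlation
#' report on dataset A.
#'
#' Every probe exclusion along the way (too few samples, zero mean, constant
#' values) is counted in the report; nothing is dropped silently. Two runs
#' with the same config produce identical reports.
#'
#' @param config a config list, or path to a config file
#'   ([read_pipeline_config()]).
#' @param matrices optional list `(a, b)` of [expression_matrix()] objects,
#'   overriding `input.*`/`simulate.*`.
#' @param out_dir optional directory; when given, intermediate tables, the
#'   bootstrap null, the parameter log and a structured text report are
#'   written there.
#' @return A list of class `pipeline_report`; see the `sections` element for
#'   a map of its contents.
#' @export
run_pipeline <- function(config = default_pipeline_config(), matrices = NULL,
                         out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- read_pipeline_config(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  stage <- "input"
  res <- tryCatch({
    if (!is.null(matrices)) {
      a <- matrices$a; b <- matrices$b
      truth <- matrices$truth
    } else if (nzchar(cfg$input.a) || nzchar(cfg$input.b)) {
      if (!nzchar(cfg$input.a) || !nzchar(cfg$input.b))
        stop("both input.a and input.b must be set (or neither)")
      a <- read_series_matrix(cfg$input.a, species_label = "dataset-A")
      b <- read_series_matrix(cfg$input.b, species_label = "dataset-B")
      truth <- NULL
    } else {
      sim_keys <- names(unclass(sim_config()))
      sim <- simulate_pair(do.call(sim_config,
        stats::setNames(cfg[paste0("simulate.", sim_keys)], sim_keys)))
      a <- sim$a; b <- sim$b; truth <- sim$truth
    }

    stage <- "cross_normalize"
    mu_assumed <- pooled_assumed_mean(a, b)
    formula <- match.arg(cfg$normalization.formula, c("scaled", "conventional"))
    za <- z_transform(a, z_params(a, mu_assumed), formula = formula)
    zb <- z_transform(b, z_params(b, mu_assumed), formula = formula)

    stage <- "variation_rank"
    cv_a <- rank_ascending(probe_cv(za, cfg$cv.min_samples))
    cv_b <- rank_ascending(probe_cv(zb, cfg$cv.min_samples))
    common_universe <- intersect(cv_a$probe_id, cv_b$probe_id)
    cv_spearman <- spearman_with_ztest(
      cv_a$cv[match(common_universe, cv_a$probe_id)],
      cv_b$cv[match(common_universe, cv_b$probe_id)])
    rank_diff <- if (identical(sort(cv_a$probe_id), sort(cv_b$probe_id)))
      rank_difference(cv_a, cv_b) else NULL
    dec_a <- lowest_decile(cv_a, cfg$cv.fraction, label = "CV10-A")
    dec_b <- lowest_decile(cv_b, cfg$cv.fraction, label = "CV10-B")
    overlap <- decile_overlap(dec_a, dec_b)

    stage <- "normfinder"
    mode <- cfg$normfinder.mode
    mode <- match.arg(mode, c("auto", "grouped", "ungrouped"))
    if (mode == "auto") {
      has_groups <- function(m) !is.null(m$group_labels) &&
        length(unique(m$group_labels)) >= 2L
      mode <- if (has_groups(a) && has_groups(b)) "grouped" else "ungrouped"
    }
    stab <- function(zm, probes, label) {
      if (mode == "grouped")
        stability_grouped(zm, zm$group_labels, probes = probes, label = label)
      else stability_ungrouped(zm, probes = probes, label = label)
    }
    nf_a <- stab(za, dec_a, "NF-A")
    nf_b <- stab(zb, dec_b, "NF-B")
    have_common <- length(overlap$probe_ids) >= 3L
    nfc_a <- if (have_common) stab(za, overlap$probe_ids, "NFC-A") else NULL
    nfc_b <- if (have_common) stab(zb, overlap$probe_ids, "NFC-B") else NULL
    all_a <- if (isTRUE(cfg$normfinder.all_probes)) stab(za, NULL, "ALL-A") else NULL
    all_b <- if (isTRUE(cfg$normfinder.all_probes)) stab(zb, NULL, "ALL-B") else NULL
    k_top <- min(cfg$normfinder.k_top, nrow(nf_a), nrow(nf_b),
                 if (have_common) c(nrow(nfc_a), nrow(nfc_b)))
    top_overlap_a <- if (have_common) top_k_overlap(nf_a, nfc_a, k_top) else NULL
    top_overlap_b <- if (have_common) top_k_overlap(nf_b, nfc_b, k_top) else NULL
    nfc_spearman <- if (have_common && nrow(nfc_a) >= 4L) {
      ids <- intersect(nfc_a$probe_id, nfc_b$probe_id)
      spearman_with_ztest(nfc_a$stability[match(ids, nfc_a$probe_id)],
                          nfc_b$stability[match(ids, nfc_b$probe_id)])
    } else NULL

    stage <- "overlap_boot"
    null_pcts <- bootstrap_null(dec_a, dec_b, n_boot = cfg$bootstrap.n,
                                scheme = cfg$bootstrap.scheme,
                                seed = cfg$bootstrap.seed,
                                universe = common_universe)
    boot_test <- overlap_ztest(overlap$percent, null_pcts, overlap$count)

    stage <- "invariant_correlation"
    corr <- correlation_report(za, nf_a, k = cfg$correlation.k,
                               n_replicates = cfg$correlation.replicates,
                               seed = cfg$correlation.seed)

    structure(list(
      schema_version = "1",
      config = cfg,
      datasets = list(
        a = list(label = a$species_label, n_probes = nrow(a$values),
                 n_samples = ncol(a$values), n_missing = sum(is.na(a$values))),
        b = list(label = b$species_label, n_probes = nrow(b$values),
                 n_samples = ncol(b$values), n_missing = sum(is.na(b$values)))),
      truth = truth,
      normalization = list(formula = formula, mu_assumed = mu_assumed,
                           sd_a = za$params$sd_dataset,
                           sd_b = zb$params$sd_dataset),
      cv = list(a = cv_a, b = cv_b, rank_difference = rank_diff,
                spearman = cv_spearman,
                excluded_a = attr(cv_a, "excluded"),
                excluded_b = attr(cv_b, "excluded")),
      deciles = list(a = dec_a, b = dec_b, overlap = overlap),
      stability = list(mode = mode, nf_a = nf_a, nf_b = nf_b,
                       nfc_a = nfc_a, nfc_b = nfc_b,
                       all_a = all_a, all_b = all_b,
                       top_k = k_top,
                       top_overlap_a = top_overlap_a,
                       top_overlap_b = top_overlap_b,
                       nfc_spearman = nfc_spearman),
      overlap_test = boot_test,
      bootstrap_null = as.numeric(null_pcts),
      correlation = corr,
      sections = c("datasets", "normalization", "cv", "deciles", "stability",
                   "overlap_test", "correlation")),
      class = "pipeline_report")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Where a probe ranks across the stability tables
#'
#' Looks a probe up in every stability table of a pipeline report and lists
#' its rank in each, or `"absent"` where the probe did not enter the table.
#'
#' @param report a `pipeline_report`.
#' @param probe probe ID (canonicalized before lookup).
#' @return data.frame `(list_label, rank)` with one row per table.
#' @export
compare_rank_placement <- function(report, probe) {
  probe <- canonical_probe_id(probe)
  tabs <- report$stability[c("nf_a", "nf_b", "nfc_a", "nfc_b", "all_a", "all_b")]
  tabs <- tabs[!vapply(tabs, is.null, logical(1L))]
  if (length(tabs) == 0L) stop("report contains no stability tables")
  known <- unique(unlist(lapply(tabs, `[[`, "probe_id")))
  if (!probe %in% known) stop("unknown probe: ", probe)
  data.frame(
    list_label = vapply(tabs, attr, character(1L), "label"),
    rank = vapply(tabs, function(t) {
      i <- match(probe, t$probe_id)
      if (is.na(i)) "absent" else as.character(t$rank[i])
    }, character(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
}

write_pipeline_outputs <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_results_table(report$cv$a, p("cv_a.tsv"), digits = NA)
  write_results_table(report$cv$b, p("cv_b.tsv"), digits = NA)
  writeLines(report$deciles$a$probe_ids, p("decile_a.txt"))
  writeLines(report$deciles$b$probe_ids, p("decile_b.txt"))
  writeLines(report$deciles$overlap$probe_ids, p("decile_common.txt"))
  for (nm in c("nf_a", "nf_b", "nfc_a", "nfc_b", "all_a", "all_b")) {
    t <- report$stability[[nm]]
    if (!is.null(t)) write_results_table(t, p(paste0(nm, ".tsv")))
  }
  writeLines(formatC(report$bootstrap_null, format = "g", digits = 10),
             p("bootstrap_null.txt"))
  writeLines(c(sprintf("mu_assumed: %.15g", report$normalization$mu_assumed),
               sprintf("sd_a: %.15g", report$normalization$sd_a),
               sprintf("sd_b: %.15g", report$normalization$sd_b),
               sprintf("formula: %s", report$normalization$formula)),
             p("normalization_params.txt"))
  write_pipeline_config(report$config, p("config_echo.txt"))
  utils::capture.output(print(report), file = p("report.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Reference-gene stability pipeline report (schema", x$schema_version, ")\n")
  for (d in x$datasets)
    cat(sprintf("  dataset %s: %d probes x %d samples (%d missing cells)\n",
                d$label, d$n_probes, d$n_samples, d$n_missing))
  cat(sprintf("  normalization: %s formula, mu_assumed = %.4f, sd = %.4f / %.4f\n",
              x$normalization$formula, x$normalization$mu_assumed,
              x$normalization$sd_a, x$normalization$sd_b))
  cat(sprintf("  CV Spearman: rho = %.3f, p = %.3g (n = %d)\n",
              x$cv$spearman$rho, x$cv$spearman$p_two_sided, x$cv$spearman$n))
  cat(sprintf("  deciles: |A| = %d, |B| = %d, overlap %d probes (%.1f%%)\n",
              length(x$deciles$a$probe_ids), length(x$deciles$b$probe_ids),
              x$deciles$overlap$count, x$deciles$overlap$percent))
  print(x$overlap_test)
  if (!is.null(x$stability$top_overlap_a))
    cat(sprintf("  top-%d overlap own-vs-common: A = %d, B = %d\n",
                x$stability$top_k, x$stability$top_overlap_a$count,
                x$stability$top_overlap_b$count))
  if (!is.null(x$stability$nfc_spearman))
    cat(sprintf("  common-list stability Spearman: rho = %.3f, p = %.3g\n",
                x$stability$nfc_spearman$rho, x$stability$nfc_spearman$p_two_sided))
  print(x$correlation)
  invisible(x)
}
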