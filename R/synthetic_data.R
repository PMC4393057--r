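#' Configuration for the paired-dataset simulator
#'
#' Defaults mirror the shape of the two ground-squirrel liver series the
#' pipeline was designed around: a shared platform of 12575 probes, one
#' dataset of 26 samples and one of 35, and three physiological-state groups
#' (summer, interbout arousal, late torpor).
#'
#' Per probe, a baseline level is drawn once and shared by both datasets; each
#' dataset then adds its own per-probe group mean shifts and Gaussian noise
#' whose standard deviation is probe specific. A `stable_fraction` of probes
#' per dataset is planted as expressionally stable: they receive the minimal
#' noise level `noise_sd_low` and no group shifts (an invariant probe does not
#' respond to physiological state). All other probes draw a noise sd uniformly
#' from `(noise_sd_low, noise_sd_high]`. `share_kappa` tunes how much of the
#' stable set is shared between the two datasets: each probe stable in dataset
#' A is also stable in dataset B with probability `share_kappa`, and the
#' remainder of B's stable set is filled uniformly from the probes not yet
#' selected, so that `share_kappa = 0` reduces to an independent uniform
#' draw.
#'
#' @param n_probes number of probes on the shared platform.
#' @param n_samples_a,n_samples_b sample counts of the two datasets.
#' @param n_groups number of sample groups; samples are split as evenly as
#'   possible across groups.
#' @param baseline_mean,baseline_sd distribution of the per-probe baseline
#'   level (log-ratio units). The nonzero default mean keeps the pooled mean
#'   of the data away from zero, which the cross-dataset transform divides by.
#' @param group_effect_sd spread of the per-probe, per-group mean shifts
#'   applied to non-stable probes (log-ratio units).
#' @param noise_sd_low,noise_sd_high bounds of the per-probe noise sd;
#'   `noise_sd_low` is the sd given to planted stable probes.
#' @param stable_fraction fraction of probes planted stable in each dataset.
#' @param share_kappa probability in `[0, 1]` that a probe stable in dataset A
#'   is also stable in dataset B (1 = identical stable sets, 0 = independent).
#' @param missing_rate per-cell probability of a missing value.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 12575L,
                       n_samples_a = 26L,
                       n_samples_b = 35L,
                       n_groups = 3L,
                       baseline_mean = 2.0,
                       baseline_sd = 0.5,
                       group_effect_sd = 0.25,
                       noise_sd_low = 0.1,
                       noise_sd_high = 1.0,
                       stable_fraction = 0.1,
                       share_kappa = 0.5,
                       missing_rate = 0.0,
                       seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes),
              n_samples_a = as.integer(n_samples_a),
              n_samples_b = as.integer(n_samples_b),
              n_groups = as.integer(n_groups),
              baseline_mean = as.numeric(baseline_mean),
              baseline_sd = as.numeric(baseline_sd),
              group_effect_sd = as.numeric(group_effect_sd),
              noise_sd_low = as.numeric(noise_sd_low),
              noise_sd_high = as.numeric(noise_sd_high),
              stable_fraction = as.numeric(stable_fraction),
              share_kappa = as.numeric(share_kappa),
              missing_rate = as.numeric(missing_rate),
              seed = as.integer(seed))
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$n_probes >= 1L, "n_probes must be positive")
  chk(cfg$n_samples_a >= 1L, "n_samples_a must be positive")
  chk(cfg$n_samples_b >= 1L, "n_samples_b must be positive")
  chk(cfg$n_groups >= 1L, "n_groups must be positive")
  chk(cfg$baseline_sd >= 0, "baseline_sd must be non-negative")
  chk(cfg$group_effect_sd >= 0, "group_effect_sd must be non-negative")
  chk(cfg$noise_sd_low >= 0, "noise_sd_low must be non-negative")
  chk(cfg$noise_sd_low < cfg$noise_sd_high,
      "noise_sd_low must be strictly below noise_sd_high")
  chk(cfg$stable_fraction >= 0 && cfg$stable_fraction <= 1,
      "stable_fraction must lie in [0, 1]")
  chk(cfg$share_kappa >= 0 && cfg$share_kappa <= 1,
      "share_kappa must lie in [0, 1]")
  chk(cfg$missing_rate >= 0 && cfg$missing_rate < 1,
      "missing_rate must lie in [0, 1)")
  chk(!is.na(cfg$seed), "seed must be an integer")
  if (length(problems) > 0L)
    stop("invalid simulation config: ", paste(problems, collapse = "; "))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a pair of related expression datasets
#'
#' Generates two probe x sample log-ratio matrices over a shared probe
#' universe, following the model described in [sim_config()]:
#' `value[i, j] = baseline[i] + gamma[i, group(j)] + e[i, j]`, with the
#' baseline shared between datasets, group shifts `gamma ~ N(0,
#' group_effect_sd^2)` for non-stable probes (0 for stable probes), and noise
#' `e ~ N(0, sd[i]^2)` with the probe's planted sd. Cells are masked missing
#' independently at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @return A list with elements `a` and `b` (two [expression_matrix()]
#'   objects, with group labels) and `truth`, a list of class `sim_truth`
#'   holding the planted stable sets (`stable_set_a`, `stable_set_b`) and the
#'   per-probe noise sds (`noise_sd_a`, `noise_sd_b`).
#' @examples
#' sim <- simulate_pair(sim_config(n_probes = 50, n_samples_a = 6,
#'                                 n_samples_b = 9, seed = 7))
#' truth_overlap_fraction(sim$truth)
#' @export
simulate_pair <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  np <- config$n_probes
  probes <- sprintf("p%05d", seq_len(np))
  n_stable <- round(config$stable_fraction * np)

  stable_a <- sort(sample.int(np, n_stable))
  keep <- stable_a[stats::runif(n_stable) < config$share_kappa]
  # remainder drawn uniformly from everything not yet selected, so that
  # share_kappa = 0 yields an independently drawn set (not a disjoint one)
  pool <- setdiff(seq_len(np), keep)
  n_fill <- n_stable - length(keep)
  stable_b <- sort(c(keep, if (n_fill > 0L) sample(pool, n_fill)))

  baseline <- stats::rnorm(np, config$baseline_mean, config$baseline_sd)
  sd_a <- draw_noise_sd(np, stable_a, config)
  sd_b <- draw_noise_sd(np, stable_b, config)

  one <- function(n_samples, noise_sd, stable_idx, label, sample_prefix) {
    groups <- sort(rep_len(seq_len(config$n_groups), n_samples))
    gamma <- matrix(stats::rnorm(np * config$n_groups, 0, config$group_effect_sd),
                    np, config$n_groups)
    gamma[stable_idx, ] <- 0
    vals <- baseline + gamma[, groups, drop = FALSE] +
      matrix(stats::rnorm(np * n_samples), np, n_samples) * noise_sd
    if (config$missing_rate > 0) {
      vals[matrix(stats::runif(np * n_samples), np, n_samples) <
             config$missing_rate] <- NA_real_
    }
    expression_matrix(vals, probes,
                      sprintf("%s%02d", sample_prefix, seq_len(n_samples)),
                      species_label = label,
                      group_labels = paste0("g", groups))
  }

  a <- one(config$n_samples_a, sd_a, stable_a, "synthetic-A", "A")
  b <- one(config$n_samples_b, sd_b, stable_b, "synthetic-B", "B")
  truth <- structure(list(stable_set_a = probes[stable_a],
                          stable_set_b = probes[stable_b],
                          noise_sd_a = stats::setNames(sd_a, probes),
                          noise_sd_b = stats::setNames(sd_b, probes),
                          config = config),
                     class = "sim_truth")
  list(a = a, b = b, truth = truth)
}

draw_noise_sd <- function(np, stable_idx, config) {
  sd <- config$noise_sd_low +
    stats::runif(np) * (config$noise_sd_high - config$noise_sd_low)
  sd[stable_idx] <- config$noise_sd_low
  sd
}

#' Fraction of dataset A's planted stable set shared with dataset B
#'
#' Ground-truth analogue of the decile-overlap statistic: the proportion of
#' probes planted stable in dataset A that were also planted stable in
#' dataset B.
#'
#' @param truth the `sim_truth` component returned by [simulate_pair()].
#' @return A fraction in `[0, 1]`.
#' @export
truth_overlap_fraction <- function(truth) {
  if (!inherits(truth, "sim_truth")) stop("truth must be a sim_truth object")
  if (length(truth$stable_set_a) == 0L)
    stop("stable_set_a is empty: overlap fraction undefined")
  length(intersect(truth$stable_set_a, truth$stable_set_b)) /
    length(truth$stable_set_a)
}
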