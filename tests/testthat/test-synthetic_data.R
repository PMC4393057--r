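test_that("config validation lists offending fields", {
  expect_error(sim_config(noise_sd_low = 1, noise_sd_high = 0.5),
               "noise_sd_low must be strictly below")
  expect_error(sim_config(share_kappa = 1.2), "share_kappa")
  expect_error(sim_config(stable_fraction = -0.1), "stable_fraction")
  err <- tryCatch(sim_config(n_probes = 0, share_kappa = 2),
                  error = conditionMessage)
  expect_match(err, "n_probes")
  expect_match(err, "share_kappa")
})

test_that("share_kappa = 1 forces identical stable sets", {
  sim <- simulate_pair(sim_config(n_probes = 100L, n_samples_a = 6L,
                                  n_samples_b = 6L, stable_fraction = 0.1,
                                  share_kappa = 1, seed = 2))
  expect_length(sim$truth$stable_set_a, 10L)
  expect_identical(sim$truth$stable_set_a, sim$truth$stable_set_b)
  expect_equal(truth_overlap_fraction(sim$truth), 1.0)
})

test_that("share_kappa = 0 overlap matches the independent-draw expectation", {
  # |A n B| ~ hypergeometric-like with mean stable_fraction * |A|
  counts <- vapply(1:6, function(s) {
    t <- simulate_pair(sim_config(n_probes = 12575L, n_samples_a = 2L,
                                  n_samples_b = 2L, share_kappa = 0,
                                  seed = s))$truth
    length(intersect(t$stable_set_a, t$stable_set_b))
  }, numeric(1L))
  expected <- 0.1 * 1258          # ~ 125.8
  sd_one <- sqrt(1258 * 0.1 * 0.9)  # ~ 10.6, binomial approximation
  expect_lt(abs(mean(counts) - expected), 4 * sd_one / sqrt(length(counts)))
})

test_that("overlap grows monotonically with share_kappa (in expectation)", {
  mean_ov <- vapply(c(0, 0.5, 1), function(kap) {
    mean(vapply(1:4, function(s)
      truth_overlap_fraction(simulate_pair(
        sim_config(n_probes = 2000L, n_samples_a = 2L, n_samples_b = 2L,
                   share_kappa = kap, seed = s))$truth), numeric(1L)))
  }, numeric(1L))
  expect_true(all(diff(mean_ov) > 0))
  expect_equal(mean_ov[3], 1.0)
})

test_that("zero-noise stable probes have zero within-group variance", {
  sim <- simulate_pair(sim_config(n_probes = 50L, n_samples_a = 9L,
                                  n_samples_b = 9L, noise_sd_low = 0,
                                  noise_sd_high = 0.5, seed = 4,
                                  share_kappa = 1))
  p <- sim$truth$stable_set_a[1]
  # stable probes carry no group effect either, so the whole row is constant
  expect_equal(stats::sd(sim$a$values[p, ]), 0)
  expect_equal(stats::sd(sim$b$values[p, ]), 0)
})

test_that("identical seeds give bit-identical datasets and truth", {
  cfg <- sim_config(n_probes = 200L, n_samples_a = 7L, n_samples_b = 8L,
                    missing_rate = 0.02, seed = 42)
  s1 <- simulate_pair(cfg)
  s2 <- simulate_pair(cfg)
  expect_identical(s1$a$values, s2$a$values)
  expect_identical(s1$b$values, s2$b$values)
  expect_identical(s1$truth$stable_set_b, s2$truth$stable_set_b)
  s3 <- simulate_pair(sim_config(n_probes = 200L, n_samples_a = 7L,
                                 n_samples_b = 8L, missing_rate = 0.02,
                                 seed = 43))
  expect_false(identical(s1$a$values, s3$a$values))
})

test_that("simulated output has the configured shape, groups and missingness", {
  cfg <- sim_config(n_probes = 300L, n_samples_a = 10L, n_samples_b = 14L,
                    n_groups = 3L, missing_rate = 0.05, seed = 6)
  sim <- simulate_pair(cfg)
  expect_equal(dim(sim$a), c(300L, 10L))
  expect_equal(dim(sim$b), c(300L, 14L))
  # samples split as evenly as possible across groups
  expect_equal(as.integer(table(sim$a$group_labels)), c(4L, 3L, 3L))
  expect_equal(as.integer(table(sim$b$group_labels)), c(5L, 5L, 4L))
  rate <- mean(is.na(c(sim$a$values, sim$b$values)))
  expect_lt(abs(rate - 0.05), 0.01)
})

test_that("truth overlap fraction handles edge sets", {
  t1 <- structure(list(stable_set_a = c("a", "b"), stable_set_b = c("c", "d")),
                  class = "sim_truth")
  expect_equal(truth_overlap_fraction(t1), 0)
  t2 <- structure(list(stable_set_a = c("a", "b"), stable_set_b = c("b", "a")),
                  class = "sim_truth")
  expect_equal(truth_overlap_fraction(t2), 1)
  t3 <- structure(list(stable_set_a = character(0), stable_set_b = "a"),
                  class = "sim_truth")
  expect_error(truth_overlap_fraction(t3), "empty")
  # a 1258-probe list sharing 178 probes: the headline overlap fraction
  t4 <- structure(list(stable_set_a = as.character(1:1258),
                       stable_set_b = as.character(c(1:178, 2000:3079))),
                  class = "sim_truth")
  expect_equal(truth_overlap_fraction(t4), 178 / 1258)
  expect_equal(round(100 * truth_overlap_fraction(t4), 1), 14.1)
})
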