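test_that("probe CV is sd/mean over non-missing values", {
  t1 <- probe_cv(matrix(c(2, 2, 2), 1, 3))
  expect_equal(t1$cv, 0)
  t2 <- probe_cv(matrix(c(1, 2, 3), 1, 3))
  expect_equal(t2$cv, 0.5)  # sd 1, mean 2
  t3 <- probe_cv(matrix(c(1, NA, 3, 4, NA, 4), 1, 6))
  expect_equal(t3$cv, sd(c(1, 3, 4, 4)) / 3, tolerance = 1e-12)
  expect_equal(t3$cv, 0.4714, tolerance = 1e-4)
  expect_equal(t3$n_used, 4)
})

test_that("probes with too few samples or zero mean are excluded and logged", {
  m <- rbind(a = c(1, 2, 3), b = c(4, NA, NA), d = c(-1, 0, 1))
  t <- probe_cv(m, min_samples = 3L)
  expect_equal(t$probe_id, "a")
  exc <- attr(t, "excluded")
  expect_setequal(exc$probe_id, c("b", "d"))
  expect_equal(exc$reason[exc$probe_id == "b"], "too-few-samples")
  expect_equal(exc$reason[exc$probe_id == "d"], "zero-mean")
})

test_that("ascending ranks use the average-tie convention", {
  mk <- function(cvs) {
    t <- data.frame(probe_id = sprintf("p%d", seq_along(cvs)), cv = cvs)
    rank_ascending(t)$rank
  }
  expect_equal(mk(c(0.1, 0.3, 0.2)), c(1, 3, 2))
  expect_equal(mk(c(0.1, 0.1, 0.5)), c(1.5, 1.5, 3))
  expect_equal(mk(rep(0.2, 4)), rep(2.5, 4))
  # rank sum invariant N(N+1)/2 even with ties
  set.seed(8)
  cvs <- sample(round(runif(200), 2))
  expect_equal(sum(mk(cvs)), 200 * 201 / 2)
})

test_that("rank differences are signed, conserved, and demand one universe", {
  t <- rank_ascending(data.frame(probe_id = c("a", "b"), cv = c(0.1, 0.2)))
  expect_equal(rank_difference(t, t)$rank_diff, c(0, 0))
  t2 <- rank_ascending(data.frame(probe_id = c("a", "b"), cv = c(0.2, 0.1)))
  expect_equal(rank_difference(t, t2)$rank_diff, c(-1, 1))
  set.seed(9)
  big_a <- rank_ascending(data.frame(probe_id = sprintf("p%03d", 1:50),
                                     cv = runif(50)))
  big_b <- rank_ascending(data.frame(probe_id = sprintf("p%03d", 1:50),
                                     cv = runif(50)))
  expect_equal(sum(rank_difference(big_a, big_b)$rank_diff), 0)
  t3 <- rank_ascending(data.frame(probe_id = c("a", "zz"), cv = c(0.1, 0.2)))
  expect_error(rank_difference(t, t3), "symmetric difference: .*zz")
})

test_that("decile size rounds half away from zero", {
  mk <- function(n) rank_ascending(
    data.frame(probe_id = sprintf("p%05d", seq_len(n)), cv = seq_len(n) / n))
  expect_length(lowest_decile(mk(12575))$probe_ids, 1258L)
  expect_length(lowest_decile(mk(10))$probe_ids, 1L)
  expect_length(lowest_decile(mk(25))$probe_ids, 3L)  # 2.5 rounds up
  expect_error(lowest_decile(mk(10), fraction = 0), "fraction")
  expect_error(lowest_decile(mk(10), fraction = 1.5), "fraction")
})

test_that("boundary ties in decile selection break lexicographically", {
  t <- data.frame(probe_id = c("z9", "a1", "m5", "b2"),
                  cv = c(0.2, 0.2, 0.1, 0.9))
  d <- lowest_decile(rank_ascending(t), fraction = 0.5)
  # m5 first on cv; tie between a1 and z9 resolved in favour of a1
  expect_setequal(d$probe_ids, c("a1", "m5"))
})

test_that("decile overlap is an exact set intersection with |A| denominator", {
  d <- function(ids) structure(list(probe_ids = ids), class = "decile_set")
  same <- d(sprintf("p%d", 1:30))
  expect_equal(decile_overlap(same, same)$percent, 100)
  expect_equal(decile_overlap(d(c("a", "b")), d(c("c", "d")))$count, 0)
  ov <- decile_overlap(d(as.character(1:1258)),
                       d(as.character(c(1:178, 5000:6079))))
  expect_equal(ov$count, 178L)
  expect_equal(ov$percent, 100 * 178 / 1258)
  expect_equal(round(ov$percent, 1), 14.1)
  # brute-force cross-check on random small sets
  set.seed(10)
  for (i in 1:10) {
    u <- sprintf("p%03d", 1:60)
    A <- sample(u, 20); B <- sample(u, 20)
    brute <- sum(vapply(A, function(x) x %in% B, logical(1)))
    expect_equal(decile_overlap(d(A), d(B))$count, brute)
  }
  expect_warning(decile_overlap(d(c("a", "b", "c")), d(c("a"))), "size")
})

test_that("Spearman rho matches the classical rank formula and base R", {
  r <- spearman_with_ztest(1:4, c(1, 3, 2, 4))
  expect_equal(r$rho, 1 - 6 * 2 / (4 * 15))  # = 0.8
  expect_equal(spearman_with_ztest(1:10, 10:1)$rho, -1)
  set.seed(11)
  x <- rnorm(40); y <- x + rnorm(40)
  expect_equal(spearman_with_ztest(x, y)$rho,
               cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(spearman_with_ztest(x, x)$rho, 1)
  # antisymmetry under reversing y
  expect_equal(spearman_with_ztest(x, -y)$rho, -spearman_with_ztest(x, y)$rho)
  expect_error(spearman_with_ztest(1:3, c(2, 1, 3)), "at least 4")
  expect_error(spearman_with_ztest(1:5, rep(2, 5)), "constant")
})

test_that("the Fisher z-test reproduces published p-value magnitudes", {
  # rho = 0.322 at n = 178: z = atanh(0.322) * sqrt(175)
  z <- atanh(0.322) * sqrt(175)
  expect_equal(z, 4.42, tolerance = 1e-2)
  p <- 2 * pnorm(-z)
  expect_lt(abs(log10(p) - log10(1e-5)), log10(2))  # within a factor of 2
  # rho = 0.141 at n = 12575 gives a p-value of order 1e-56
  z2 <- atanh(0.141) * sqrt(12572)
  p2 <- 2 * pnorm(-z2)
  expect_lt(p2, 1e-50)
  expect_gt(p2, 1e-60)
})
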