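test_that("ungrouped stability is the across-sample sd, ranked ascending", {
  t <- stability_ungrouped(rbind(a = rep(5, 4), b = c(1, 2, 3, 4)))
  expect_equal(t$stability[t$probe_id == "a"], 0)
  expect_equal(t$rank[t$probe_id == "a"], 1L)
  t2 <- stability_ungrouped(matrix(c(1, 2, 3), 1, 3))
  expect_equal(t2$stability, 1.0)
  t3 <- stability_ungrouped(rbind(x = rnorm(5) * 0 + c(1, 1, 1.2, 1, 1),
                                  y = c(0, 2, 0, 2, 0)))
  expect_equal(t3$probe_id[t3$rank == 1L], "x")
})

test_that("probes with insufficient data are excluded and logged", {
  m <- rbind(a = c(1, 2, 3), b = c(4, NA, NA))
  t <- stability_ungrouped(m)
  expect_equal(t$probe_id, "a")
  expect_equal(attr(t, "excluded"), "b")
})

test_that("a zero-variance zero-deviation probe attains the minimum index", {
  set.seed(21)
  y <- matrix(rnorm(96, 3, 0.6), 12, 8)
  shift <- rep(c(0.5, -0.5), 2)  # balanced real group deviations
  y[1:4, ] <- y[1:4, ] + outer(shift, rep(c(1, -1), each = 4))
  y[6, ] <- 3  # flat in every group: the perfect reference probe
  rownames(y) <- sprintf("g%02d", 1:12)
  t <- stability_grouped(y, rep(c("s", "t"), each = 4))
  expect_equal(t$probe_id[t$rank == 1L], "g06")
  expect_equal(min(t$stability), t$stability[t$probe_id == "g06"])
})

test_that("grouped indices match the loop-wise oracle on toy matrices", {
  for (case in 1:3) {
    toy <- oracle_toy_matrix(case)
    want <- oracle_grouped_stability(toy$y, toy$groups)
    got <- stability_grouped(toy$y, toy$groups)
    expect_equal(got$stability[match(names(want), got$probe_id)],
                 unname(want), tolerance = 1e-6)
  }
})

test_that("grouped indices reproduce the frozen golden fixture", {
  # frozen from oracle_grouped_stability(oracle_toy_matrix(1))
  golden <- c(t01 = 0.72565124, t02 = 0.80335093, t03 = 0.07019544,
              t04 = 0.56751919, t05 = 0.83744936)
  toy <- oracle_toy_matrix(1)
  got <- stability_grouped(toy$y, toy$groups)
  expect_equal(got$stability[match(names(golden), got$probe_id)],
               unname(golden), tolerance = 1e-6)
  # the low-noise probe t03 is the most stable; the group-shifted t02 is not
  expect_equal(got$probe_id[got$rank == 1L], "t03")
})

test_that("permuting samples within groups leaves the result unchanged", {
  toy <- oracle_toy_matrix(2)
  base <- stability_grouped(toy$y, toy$groups)
  set.seed(22)
  perm <- c(sample(1:3), sample(4:6), sample(7:9))
  shuf <- stability_grouped(toy$y[, perm], toy$groups[perm])
  expect_equal(shuf$stability[match(base$probe_id, shuf$probe_id)],
               base$stability, tolerance = 1e-12)
})

test_that("stability scales linearly with the data scale in both modes", {
  toy <- oracle_toy_matrix(2)
  for (c_scale in c(0.5, 3)) {
    g1 <- stability_grouped(toy$y, toy$groups)
    g2 <- stability_grouped(toy$y * c_scale, toy$groups)
    expect_equal(g2$stability, c_scale * g1$stability, tolerance = 1e-10)
    u1 <- stability_ungrouped(toy$y)
    u2 <- stability_ungrouped(toy$y * c_scale)
    expect_equal(u2$stability, c_scale * u1$stability, tolerance = 1e-10)
  }
})

test_that("both modes recover a planted noise-sd ordering", {
  sim <- simulate_pair(sim_config(n_probes = 800L, n_samples_a = 24L,
                                  n_samples_b = 24L, group_effect_sd = 0,
                                  seed = 23))
  sp_u <- cor(stability_ungrouped(sim$a)$stability,
              sim$truth$noise_sd_a[stability_ungrouped(sim$a)$probe_id],
              method = "spearman")
  st_g <- stability_grouped(sim$a, sim$a$group_labels)
  sp_g <- cor(st_g$stability, sim$truth$noise_sd_a[st_g$probe_id],
              method = "spearman")
  expect_gt(sp_u, 0.95)
  expect_gt(sp_g, 0.95)
})

test_that("grouped mode validates its design requirements", {
  y <- matrix(rnorm(12), 3, 4, dimnames = list(c("a", "b", "d"), NULL))
  expect_error(stability_grouped(y, c("g1", "g1", "g1", "g2")),
               "at least 2 samples.*g2")
  expect_error(stability_grouped(y, rep("g1", 4)), "at least 2 groups")
  expect_error(stability_grouped(y[1:2, ], rep(c("g1", "g2"), each = 2)),
               "at least 3 candidate probes")
  expect_error(stability_grouped(y, rep(c("g1", "g2"), each = 2),
                                 probes = c("a", "nope")), "not in the")
})

test_that("ranking breaks ties lexicographically and covers 1..N", {
  t <- new_tab <- data.frame(probe_id = c("b", "a", "c"),
                             stability = c(0.2, 0.2, 0.1))
  class(t) <- c("stability_table", "data.frame")
  r <- rank_stability(t)
  expect_equal(r$probe_id, c("c", "a", "b"))
  expect_equal(r$rank, 1:3)
  # indices {0.167, 0.195} rank in ascending-index order
  t2 <- data.frame(probe_id = c("02n12", "13d19"), stability = c(0.167, 0.195))
  class(t2) <- c("stability_table", "data.frame")
  expect_equal(rank_stability(t2)$rank, c(1L, 2L))
})

test_that("top-k overlap intersects the k most stable probes", {
  mk <- function(ids, idx) {
    t <- data.frame(probe_id = ids, stability = idx)
    class(t) <- c("stability_table", "data.frame")
    rank_stability(t)
  }
  a <- mk(sprintf("p%02d", 1:30), seq(0.1, 3, length.out = 30))
  expect_equal(top_k_overlap(a, a, 20)$count, 20L)
  b <- mk(sprintf("p%02d", 1:30), rev(seq(0.1, 3, length.out = 30)))
  # a's top 20 = p01..p20; b's top 20 = p11..p30; overlap = 10
  expect_equal(top_k_overlap(a, b, 20)$count, 10L)
  expect_setequal(top_k_overlap(a, b, 20)$probe_ids, sprintf("p%02d", 11:20))
  expect_error(top_k_overlap(a, b, 31), "k must lie")
})
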