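# Independent, formula-literal oracle for the grouped stability model.
# Written loop-wise, element by element, deliberately sharing no code with
# the package's vectorized implementation. This is a synthetic oracle: it
# encodes the published variance-decomposition model directly from its
# formulas (with the package's standard-error spread term) and pins the
# estimator constants the implementation must reproduce.
oracle_grouped_stability <- function(y, groups) {
  k <- nrow(y)
  glev <- unique(groups)
  G <- length(glev)
  sigma2 <- matrix(0, k, G)
  zmean <- matrix(0, k, G)
  ng <- matrix(0, k, G)
  for (gi in seq_len(G)) {
    cols <- which(groups == glev[gi])
    n <- length(cols)
    sub <- y[, cols, drop = FALSE]
    grand <- mean(sub)
    s2 <- numeric(k)
    for (i in seq_len(k)) {
      ri2 <- 0
      for (j in seq_len(n)) {
        res <- sub[i, j] - mean(sub[i, ]) - mean(sub[, j]) + grand
        ri2 <- ri2 + res^2
      }
      s2[i] <- ri2 / (n - 1)
      zmean[i, gi] <- mean(sub[i, ])
      ng[i, gi] <- n
    }
    for (i in seq_len(k))
      sigma2[i, gi] <- max(k / (k - 2) * (s2[i] - mean(s2) / (k - 1)), 0)
  }
  d <- matrix(0, k, G)
  for (i in seq_len(k)) for (gi in seq_len(G))
    d[i, gi] <- zmean[i, gi] - mean(zmean[i, ]) - mean(zmean[, gi]) + mean(zmean)
  vard <- sigma2 / ng
  gamma2 <- max(0, sum(d^2) / ((k - 1) * (G - 1)) - mean(vard))
  rho <- numeric(k)
  for (i in seq_len(k)) {
    acc <- 0
    for (gi in seq_len(G)) {
      dt <- d[i, gi] * gamma2 / (gamma2 + vard[i, gi])
      if (gamma2 + vard[i, gi] == 0) dt <- 0
      acc <- acc + abs(dt) + sqrt(vard[i, gi])
    }
    rho[i] <- acc / G
  }
  names(rho) <- rownames(y)
  rho
}

# Deterministic toy matrices used for golden-fixture comparisons.
oracle_toy_matrix <- function(case) {
  switch(as.character(case),
    "1" = { # 5 probes, 2 groups x 4 samples, mild group shifts
      set.seed(401)
      y <- matrix(rnorm(40, 5, 1), 5, 8)
      y[2, ] <- 5 + c(rep(0.8, 4), rep(-0.8, 4)) + rnorm(8, 0, 0.2)
      y[3, ] <- rnorm(8, 5, 0.05)
      list(y = nm_name(y), groups = rep(c("g1", "g2"), each = 4))
    },
    "2" = { # 6 probes, 3 groups of 3, heteroscedastic
      set.seed(402)
      sds <- c(0.05, 0.2, 0.4, 0.6, 1.0, 1.5)
      y <- t(sapply(sds, function(s) rnorm(9, 4, s)))
      list(y = nm_name(y), groups = rep(c("a", "b", "c"), each = 3))
    },
    "3" = { # 4 probes, 2 unequal groups (3 + 5)
      set.seed(403)
      y <- matrix(rnorm(32, 2, 0.5), 4, 8)
      y[1, ] <- 2 + c(rep(-0.5, 3), rep(0.5, 5)) + rnorm(8, 0, 0.1)
      list(y = nm_name(y), groups = rep(c("g1", "g2"), c(3, 5)))
    },
    stop("unknown toy case"))
}

nm_name <- function(y) {
  rownames(y) <- sprintf("t%02d", seq_len(nrow(y)))
  colnames(y) <- sprintf("s%02d", seq_len(ncol(y)))
  y
}
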