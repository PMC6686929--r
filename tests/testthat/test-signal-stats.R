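test_that("Moran's I matches hand values and the double-loop oracle", {
  W2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(moran_i(c(a = 1, b = -1), W2, n_perm = 0)$value, -1)

  tr10 <- generate_tree(10, seed = 31)
  W10 <- proximity_matrix(patristic_distances(tr10))
  est <- moran_i(simulate_trait(tr10, "BM", seed = 32), W10, n_perm = 99,
                 seed = 1)
  expect_equal(est$null_expectation, -1 / 9)
  expect_equal(round(est$null_expectation, 3), -0.111)
  expect_gt(est$p_value, 0)
  expect_lte(est$p_value, 1)

  set.seed(13)
  for (n in 3:12) {
    D <- as.matrix(dist(matrix(runif(n * 2), n)))
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    W <- proximity_matrix(D)
    x <- setNames(rnorm(n), rownames(W))
    expect_equal(moran_i(x, W, n_perm = 0)$value, moran_oracle(x, W),
                 tolerance = 1e-12)
  }

  expect_error(moran_i(setNames(rep(1, 10), rownames(W10)), W10),
               "zero variance")
})

test_that("mean Moran's I over all tip permutations equals -1/(n-1) exactly", {
  for (n in c(4, 5)) {
    set.seed(n)
    D <- as.matrix(dist(matrix(runif(n * 2), n)))
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    W <- proximity_matrix(D)
    x <- rnorm(n)
    vals <- vapply(all_perms(n), function(p) {
      moran_i(setNames(x[p], rownames(W)), W, n_perm = 0)$value
    }, numeric(1))
    expect_equal(mean(vals), -1 / (n - 1), tolerance = 1e-12)
  }
})

test_that("Blomberg's K is exactly 1 on equal-depth star trees", {
  for (n in c(5, 8, 16)) {
    C <- bm_covariance(star_tree(n, depth = 0.7))
    set.seed(n)
    for (rep in 1:5) {
      x <- setNames(rnorm(n), rownames(C))
      expect_equal(blomberg_k(x, C, n_perm = 0)$value, 1, tolerance = 1e-10)
    }
  }
})

test_that("K and lambda agree with phytools::phylosig", {
  set.seed(17)
  for (rep in 1:4) {
    tr <- generate_tree(16, seed = 40 + rep)
    C <- bm_covariance(tr)
    x <- simulate_trait(tr, "BM", seed = 50 + rep)
    expect_equal(blomberg_k(x, C, n_perm = 0)$value,
                 unclass(phytools::phylosig(tr, x, method = "K"))[[1]],
                 tolerance = 1e-6)
    pl <- pagel_lambda(x, C)
    ps <- phytools::phylosig(tr, x, method = "lambda")
    expect_equal(pl$value, ps$lambda, tolerance = 1e-4)
    expect_equal(pl$lnL, ps$logL, tolerance = 1e-6)
  }
})

test_that("K under BM averages 1 and randomized traits on a pectinate tree give K < 1", {
  tree32 <- generate_tree(32, seed = 101)
  C <- bm_covariance(tree32)
  set.seed(61)
  ks <- replicate(300, blomberg_k(simulate_trait(tree32, "BM"), C,
                                  n_perm = 0)$value)
  expect_equal(mean(ks), 1, tolerance = 0.05)

  # deep comb (pectinate) tree: shuffled tip values lose the clade structure
  comb <- ape::compute.brlen(ape::stree(16, type = "left"), power = 1)
  comb <- normalize_depth(comb, tol = 1)
  Cc <- bm_covariance(comb)
  set.seed(62)
  below <- replicate(100, {
    x <- setNames(rnorm(16), rownames(Cc))
    blomberg_k(x, Cc, n_perm = 0)$value < 1
  })
  expect_gte(mean(below), 0.95)
})

test_that("lambda = 0 reduces to the iid-normal likelihood and matches grid search", {
  tr <- generate_tree(24, seed = 71)
  C <- bm_covariance(tr)
  x <- simulate_trait(tr, "BM", seed = 72)
  est <- pagel_lambda(x, C)
  # closed-form iid likelihood at lambda = 0 (variance profile T * sigma2)
  n <- length(x)
  Tdepth <- C[1, 1]
  s2 <- sum((x - mean(x))^2) / n
  lnl0 <- -0.5 * (n * log(2 * pi * s2) + n)
  expect_equal(est$lnL0, lnl0 - 0, tolerance = 1e-8)

  # profile optimum matches a fine grid search
  set.seed(73)
  for (rep in 1:10) {
    tr <- generate_tree(12, seed = 80 + rep)
    C <- bm_covariance(tr)
    x <- setNames(rnorm(12) + simulate_trait(tr, "BM"), rownames(C))
    est <- pagel_lambda(x, C)
    grid <- seq(0, est$lambda_max, by = 1e-3)
    lnls <- vapply(grid, function(l) {
      V <- C * l; diag(V) <- diag(C)
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(-Inf)
      one <- rep(1, 12)
      Vi <- chol2inv(ch)
      z0 <- sum(Vi %*% x) / sum(Vi)
      q <- drop(t(x - z0) %*% Vi %*% (x - z0))
      -0.5 * (12 * log(2 * pi * q / 12) + 2 * sum(log(diag(ch))) + 12)
    }, numeric(1))
    expect_equal(est$value, grid[which.max(lnls)], tolerance = 2e-3)
  }
})

test_that("lambda = 1 log-likelihood equals the BM fit's maximized likelihood", {
  tr <- generate_tree(20, seed = 91)
  C <- bm_covariance(tr)
  x <- simulate_trait(tr, "BM", seed = 92)
  est <- pagel_lambda(x, C)
  bm <- fit_bm(x, C)
  if (abs(est$value - 1) < 1e-6) {
    expect_equal(est$lnL, bm$lnL, tolerance = 1e-6)
  }
  # direct identity regardless of the optimum's location
  V <- C * 1; diag(V) <- diag(C)
  expect_equal(as.numeric(lncphylo:::profile_lnl(x, V)), bm$lnL,
               tolerance = 1e-10)
})

test_that("the local correlogram has the contracted shape and sane CIs", {
  tr <- generate_tree(12, seed = 111)
  D <- patristic_distances(tr)
  x <- simulate_trait(tr, "BM", seed = 112)
  cg <- local_correlogram(x, D, n_points = 100, n_boot = 200, seed = 113)
  expect_equal(nrow(cg), 100)
  expect_true(all(diff(cg$h) > 0))
  expect_equal(max(cg$h), max(D), tolerance = 1e-12)
  expect_equal(attr(cg, "threshold"), -1 / 11)
  ok <- !is.na(cg$lo) & !is.na(cg$I)
  expect_true(any(ok))
  expect_true(all(cg$lo[ok] <= cg$hi[ok]))

  # wider interval at higher confidence level, same seed
  cg99 <- local_correlogram(x, D, n_points = 100, n_boot = 200, ci = 0.99,
                            seed = 113)
  both <- ok & !is.na(cg99$lo)
  expect_true(all(cg99$hi[both] - cg99$lo[both] >=
                    cg$hi[both] - cg$lo[both] - 1e-12))

  # deterministic under a fixed seed
  cg2 <- local_correlogram(x, D, n_points = 100, n_boot = 200, seed = 113)
  expect_equal(cg2, cg)
})

test_that("BM traits show significant positive I at short distances, permuted traits do not", {
  tree16 <- generate_tree(16, seed = 121)
  D <- patristic_distances(tree16)
  hits <- 0; null_flags <- numeric(0)
  set.seed(122)
  for (rep in 1:5) {
    x <- simulate_trait(tree16, "BM")
    cg <- local_correlogram(x, D, n_points = 50, n_boot = 150)
    short <- which(cg$h <= 0.3 * max(D))
    sig_pos <- isTRUE(any(cg$significant[short] & cg$I[short] >
                            attr(cg, "threshold"), na.rm = TRUE))
    hits <- hits + sig_pos
    xp <- setNames(sample(x), names(x))
    cgp <- local_correlogram(xp, D, n_points = 50, n_boot = 150)
    null_flags <- c(null_flags, mean(cgp$significant, na.rm = TRUE))
  }
  expect_gte(hits, 4)            # >= 80% of replicates
  expect_lte(mean(null_flags), 0.25)
})
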