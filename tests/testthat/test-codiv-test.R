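test_that("collinear points embed exactly with one positive axis", {
  x <- c(0, 1, 3)
  d <- as.matrix(dist(x))
  p <- pcoa(d)
  tol <- 1e-8 * max(p$eigenvalues)
  expect_equal(sum(p$eigenvalues > tol), 1L)
  rec <- as.matrix(dist(p$coordinates))
  expect_equal(unname(rec), unname(d), tolerance = 1e-10)
  expect_equal(p$correction_constant, 0)
})

test_that("Euclidean-embeddable distances never trigger the correction", {
  withr::with_seed(12, {
    for (rep in 1:5) {
      x <- matrix(rnorm(8 * 3), 8)
      p <- pcoa(as.matrix(dist(x)))
      expect_equal(p$correction_constant, 0)
      expect_equal(p$n_negative_pre, 0L)
      rec <- as.matrix(dist(p$coordinates))
      expect_equal(rec, unname(as.matrix(dist(x))), tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
  })
})

test_that("the Cailliez constant removes negative eigenvalues of a non-Euclidean metric", {
  # 4 points, all pairs at 1 except one pair at 2: not Euclidean-embeddable
  d <- matrix(1, 4, 4) - diag(4)
  d[1, 2] <- d[2, 1] <- 2
  raw <- pcoa(d, correction = "none")
  expect_gt(raw$n_negative_pre, 0)
  cor <- pcoa(d, correction = "cailliez_if_needed")
  expect_gt(cor$correction_constant, 0)
  expect_gte(min(cor$eigenvalues), -1e-8 * max(cor$eigenvalues))
  # off-diagonal distances all increased by the same constant
  rec <- as.matrix(dist(cor$coordinates))
  off <- upper.tri(d)
  expect_equal(rec[off], (d + cor$correction_constant)[off], tolerance = 1e-6)
})

test_that("the correction constant is minimal and agrees with ape's corrected embedding", {
  withr::with_seed(88, {
    for (rep in 1:5) {
      m <- matrix(runif(49, 0.5, 1.5), 7)
      d <- (m + t(m)) / 2
      diag(d) <- 0
      mine <- pcoa(d)
      if (mine$correction_constant == 0) next
      # a 10% smaller constant still leaves a negative eigenvalue
      d_under <- d + 0.9 * mine$correction_constant
      diag(d_under) <- 0
      under <- pcoa(d_under, correction = "none")
      expect_lt(min(under$eigenvalues), -1e-8 * max(under$eigenvalues))
      # ape's Cailliez-corrected coordinates embed d + c for the same c
      ref <- ape::pcoa(as.dist(d), correction = "cailliez")
      rec <- as.matrix(dist(ref$vectors.cor))
      c_ape <- rec[1, 2] - d[1, 2]
      expect_equal(mine$correction_constant, c_ape, tolerance = 1e-6)
    }
  })
})

test_that("a degenerate symbiont matrix gives statistic 0 and p = 1", {
  host_d <- as.matrix(dist(c(0, 1, 3, 6)))
  sym_d <- matrix(0, 4, 4)
  r <- parafit_global(host_d, sym_d, n_perm = 99, seed = 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("ParaFit on four one-to-one pairs matches exhaustive enumeration", {
  # hosts and symbionts: two tight pairs far apart, congruent structure
  x <- c(0, 0.1, 10, 10.1)
  host_d <- as.matrix(dist(x))
  sym_d <- as.matrix(dist(x))
  A <- diag(4)
  # independent statistic via ape's PCoA coordinates
  B <- ape::pcoa(as.dist(host_d))$vectors
  Cm <- ape::pcoa(as.dist(sym_d))$vectors
  stat_ext <- function(A) sum((t(Cm) %*% A %*% B)^2)
  obs <- stat_ext(A)
  perms <- gtools_permutations_4()
  stats_all <- apply(perms, 1, function(p) stat_ext(A[, p]))
  # the observed statistic is maximal; only pair-preserving relabelings tie
  expect_equal(max(stats_all), obs, tolerance = 1e-8)
  p_exhaustive <- mean(stats_all >= obs - 1e-8)
  r <- parafit_global(host_d, sym_d, A, n_perm = 2000, seed = 99,
                      scheme = "host_labels")
  expect_equal(r$statistic, obs, tolerance = 1e-8)
  se <- sqrt(p_exhaustive * (1 - p_exhaustive) / 2000)
  expect_lt(abs(r$p_value - p_exhaustive), 4 * se + 2 / 2000)
  # the default per-symbiont null agrees closely here too
  r2 <- parafit_global(host_d, sym_d, A, n_perm = 2000, seed = 99)
  expect_lt(abs(r2$p_value - p_exhaustive), 0.05)
})

test_that("the global statistic matches ape::parafit on a shared fixture", {
  withr::with_seed(5, {
    xh <- matrix(rnorm(12), 6)
    xs <- xh + matrix(rnorm(12, sd = 0.1), 6)
    host_d <- as.matrix(dist(xh))
    sym_d <- as.matrix(dist(xs))
    mine <- parafit_global(host_d, sym_d, n_perm = 499, seed = 10)
    ref <- ape::parafit(host_d, sym_d, diag(6), nperm = 499, silent = TRUE)
    expect_equal(mine$statistic, ref$ParaFitGlobal, tolerance = 1e-8)
    expect_lt(abs(mine$p_value - ref$p.global), 0.12)
  })
})

test_that("permutation p-values are never zero and are relabeling-invariant", {
  withr::with_seed(6, {
    x <- c(0, 0.2, 5, 5.2, 9, 9.3)
    host_d <- as.matrix(dist(x))
    sym_d <- as.matrix(dist(x))
    r <- parafit_global(host_d, sym_d, n_perm = 99, seed = 4)
    expect_gt(r$p_value, 0)
    # relabeling hosts and symbionts jointly preserves the statistic
    perm <- sample(6)
    r2 <- parafit_global(host_d[perm, perm], sym_d[perm, perm],
                         diag(6), n_perm = 99, seed = 4)
    expect_equal(r2$statistic, r$statistic, tolerance = 1e-8)
  })
})

test_that("Ward clustering reproduces structure and the naive linkage oracle", {
  # duplicates merge first at height zero
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9), d = c(9, 9.5, 9))
  w <- ward_cluster(m)
  expect_equal(min(w$heights), 0)
  expect_equal(w$labels_k2[["a"]], w$labels_k2[["b"]])
  expect_true(grepl("^\\(", w$newick))
  # block matrix: k = 2 cut recovers the blocks exactly
  blk <- matrix(0, 8, 4, dimnames = list(sprintf("s%d", 1:8), NULL))
  blk[1:4, 1:2] <- 0.4   # cluster A variable on SNV set 1
  blk[5:8, 3:4] <- 0.4   # cluster B variable on SNV set 2
  wb <- ward_cluster(blk)
  expect_equal(unname(wb$labels_k2[1:4]), rep(wb$labels_k2[[1]], 4))
  expect_equal(unname(wb$labels_k2[5:8]), rep(wb$labels_k2[[5]], 4))
  expect_true(wb$labels_k2[[1]] != wb$labels_k2[[5]])
  # random fixtures: merge heights equal the naive O(n^3) Ward
  withr::with_seed(303, {
    for (rep in 1:5) {
      m <- matrix(rnorm(8 * 5), 8)
      rownames(m) <- sprintf("x%d", 1:8)
      w <- ward_cluster(m)
      expect_equal(sort(w$heights), naive_ward_heights(m), tolerance = 1e-8)
    }
  })
  expect_error(ward_cluster(m[1, , drop = FALSE]), "2 samples")
})

test_that("adjusted Rand index behaves as a chance-corrected agreement score", {
  expect_equal(congruence(c(1, 1, 2, 2), c(2, 2, 1, 1))$ari, 1)
  expect_equal(congruence(c(1, 1, 2, 2), c(1, 1, 1, 1))$ari, 0)
  withr::with_seed(77, {
    aris <- vapply(1:500, function(i)
      congruence(sample(1:2, 20, TRUE), sample(1:2, 20, TRUE))$ari, 0)
    expect_lt(abs(mean(aris)), 0.05)
  })
  cg <- congruence(setNames(c(1, 1, 2, 2), c("a", "b", "c", "d")),
                   setNames(c(2, 2, 1, 1), c("c", "d", "a", "b")))
  expect_equal(cg$ari, 1)  # name-matched before comparison
})
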