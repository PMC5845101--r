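# Simple, KNN, and low-rank imputation; pass-through and support invariants.

test_that("a complete matrix passes through every method unchanged", {
  truth <- gaussian_truth(40, 4, seed = 50)
  for (meth in IMPUTE_METHODS) {
    cs <- impute(truth, method = meth, m = 2, seed = 1, iterations = 2)
    expect_identical(cs$imputations[[1]], truth)
    expect_identical(cs$imputations[[2]], truth)
  }
})

test_that("observed cells pass through bitwise and no missing cells remain", {
  md <- ampute_mcar(gaussian_truth(120, 6, rho = 0.5, seed = 51), 0.25, seed = 2)
  mv <- masked_values(md)
  for (meth in IMPUTE_METHODS) {
    cs <- suppressWarnings(impute(md, method = meth, m = 2, seed = 3,
                                  iterations = 3))
    for (imp in cs$imputations) {
      expect_false(anyNA(imp))
      expect_identical(imp[!md$mask], mv[!md$mask])
    }
  }
})

test_that("a fully missing variable is reported by name", {
  m <- gaussian_truth(20, 3, seed = 52)
  m[, "V2"] <- NA
  expect_error(impute(m, "mean"), "V2")
})

test_that("mean and median fill with the per-variable observed statistic", {
  m <- matrix(c(1, 2, 3, NA, 10, 20, NA, 40), 4, 2,
              dimnames = list(paste0("P", 1:4), c("a", "b")))
  cs_mean <- impute(m, "mean")
  expect_equal(unname(cs_mean$imputations[[1]]["P4", "a"]), 2)
  expect_equal(unname(cs_mean$imputations[[1]]["P3", "b"]), mean(c(10, 20, 40)))
  cs_med <- impute(m, "median")
  expect_equal(unname(cs_med$imputations[[1]]["P3", "b"]), 20)
})

test_that("random-sample imputations come from the observed support, independently per copy", {
  md <- ampute_mcar(gaussian_truth(300, 3, seed = 53), 0.3, seed = 4)
  cs <- impute(md, "random_sample", m = 3, seed = 5)
  for (j in 1:3) {
    obs <- md$truth[!md$mask[, j], j]
    for (imp in cs$imputations)
      expect_true(all(imp[md$mask[, j], j] %in% obs))
  }
  expect_false(identical(cs$imputations[[1]], cs$imputations[[2]]))
  cs2 <- impute(md, "random_sample", m = 3, seed = 5)
  expect_identical(cs$imputations, cs2$imputations)
})

test_that("knn copies an exact duplicate row at k = 1", {
  base <- c(1, 2, 3, 4)
  m <- rbind(r1 = base, r2 = base, r3 = c(9, 9, 9, 9))
  colnames(m) <- paste0("v", 1:4)
  m["r1", "v4"] <- NA
  cs <- impute(m, "knn", k = 1)
  expect_equal(unname(cs$imputations[[1]]["r1", "v4"]), 4)
})

test_that("knn averages the hand-identified nearest neighbours", {
  # Distances from r1 over the jointly observed v1, v2 (RMS scaling):
  # r2 at 0.1, r3 at 0.2, r4 at 5 -> k = 2 picks r2, r3.
  m <- rbind(r1 = c(1.0, 1.0, NA),
             r2 = c(1.1, 1.1, 10),
             r3 = c(1.2, 1.2, 20),
             r4 = c(6.0, 1.0, 100))
  colnames(m) <- paste0("v", 1:3)
  cs <- impute(m, "knn", k = 2)
  expect_equal(unname(cs$imputations[[1]]["r1", "v3"]), 15)
})

test_that("knn skips neighbours lacking the variable and extends the pool", {
  m <- rbind(r1 = c(1.0, NA),
             r2 = c(1.1, NA),   # nearest, but lacks v2
             r3 = c(1.3, 7),
             r4 = c(1.4, 9))
  colnames(m) <- c("v1", "v2")
  cs <- impute(m, "knn", k = 2)
  expect_equal(unname(cs$imputations[[1]]["r1", "v2"]), 8)
})

test_that("soft-impute recovers the masked cells of a rank-1 matrix", {
  set.seed(54)
  u <- rnorm(60); v <- rnorm(8)
  truth <- u %o% v
  dimnames(truth) <- list(sprintf("P%02d", 1:60), paste0("c", 1:8))
  md <- ampute_mcar(truth, 0.3, seed = 6)
  cs <- impute(md, "soft_impute", lambda = 0.01, max_iter = 500)
  imp <- cs$imputations[[1]]
  rel <- abs(imp[md$mask] - truth[md$mask]) / pmax(abs(truth[md$mask]), 1e-6)
  expect_lt(median(rel), 1e-3)
  expect_lt(mean(rel > 1e-2), 0.05)
})

test_that("a soft threshold above the top singular value collapses to mean imputation", {
  md <- ampute_mcar(gaussian_truth(50, 5, rho = 0.6, seed = 55), 0.3, seed = 7)
  x <- masked_values(md)
  mu <- colMeans(x, na.rm = TRUE)
  x0 <- sweep(x, 2, mu); x0[is.na(x0)] <- 0
  big_lambda <- svd(x0)$d[1] * 2
  cs <- impute(md, "soft_impute", lambda = big_lambda)
  cs_mean <- impute(md, "mean")
  expect_equal(cs$imputations[[1]], cs_mean$imputations[[1]], tolerance = 1e-10)
})

test_that("svd_iterative reconstructs an exactly low-rank matrix", {
  set.seed(56)
  truth <- matrix(rnorm(60 * 2), 60, 2) %*% matrix(rnorm(2 * 7), 2, 7)
  dimnames(truth) <- list(sprintf("P%02d", 1:60), paste0("c", 1:7))
  md <- ampute_mcar(truth, 0.2, seed = 8)
  cs <- impute(md, "svd_iterative", rank = 3, max_iter = 500)
  rel <- abs(cs$imputations[[1]][md$mask] - truth[md$mask]) /
    pmax(abs(truth[md$mask]), 1e-6)
  expect_lt(median(rel), 1e-3)
})

test_that("predictor pruning excludes exactly the highly correlated pairs", {
  set.seed(57)
  m <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("v", 1:4)))
  pm <- build_predictor_matrix(m, 0.85)
  expect_equal(unname(diag(pm)), rep(0, 4))
  expect_true(all(pm[upper.tri(pm)] == 1))  # orthogonal -> all allowed

  m2 <- cbind(m, v5 = m[, "v1"])  # duplicated pair
  pm2 <- build_predictor_matrix(m2, 0.85)
  expect_equal(pm2["v1", "v5"], 0)
  expect_equal(pm2["v5", "v1"], 0)

  # one pair at r ~ 0.9, all else weak
  x <- rnorm(500)
  m3 <- cbind(a = x, b = 0.9 * x + sqrt(1 - 0.81) * rnorm(500),
              c = rnorm(500), d = rnorm(500))
  cm <- abs(cor(m3)); diag(cm) <- 0
  stopifnot(cm["a", "b"] > 0.85, max(cm[cm != cm["a", "b"]]) < 0.85)
  pm3 <- build_predictor_matrix(m3, 0.85)
  expect_equal(pm3["a", "b"], 0)
  expect_equal(pm3["b", "a"], 0)
  expect_equal(sum(pm3 == 0), 4 + 2)  # diagonal + the one pruned pair
})
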