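# Amputation mechanisms: MCAR, MAR, MNAR, realistic pattern copying.

test_that("MCAR removal rate sits inside its 99% binomial interval", {
  truth <- gaussian_truth(1000, 10, seed = 30)
  md <- ampute_mcar(truth, p = 0.3, seed = 1)
  n <- length(truth)
  half_ci <- qnorm(0.995) * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(md$mask) - 0.3), half_ci)
  expect_identical(ampute_mcar(truth, 0.3, seed = 7)$mask,
                   ampute_mcar(truth, 0.3, seed = 7)$mask)
  expect_error(ampute_mcar(truth, 0), "p")
  expect_error(ampute_mcar(truth, 1.2), "p")
})

test_that("MCAR masks are independent of the cell values", {
  truth <- gaussian_truth(2000, 5, seed = 31)
  md <- ampute_mcar(truth, 0.4, seed = 3)
  pb <- cor(as.numeric(md$mask), as.numeric(md$truth))
  expect_lt(abs(pb), 0.03)
})

test_that("the MCAR grid enumerates levels x replicates", {
  truth <- gaussian_truth(30, 4, seed = 32)
  expect_length(mcar_grid(truth, seed = 1), 50)
  expect_length(mcar_grid(truth, levels = 0.5, reps = 1, seed = 1), 1)
  g <- mcar_grid(truth, levels = c(0.1, 0.2), reps = 2, seed = 1)
  expect_length(g, 4)
  expect_identical(g, mcar_grid(truth, levels = c(0.1, 0.2), reps = 2, seed = 1))
})

test_that("MAR amputation removes col_b only for rows in col_a's quartile", {
  truth <- matrix(c(8:1, rnorm(8)), 8, 2,
                  dimnames = list(paste0("P", 1:8), c("a", "b")))
  md <- ampute_mar(truth, "a", "b", quartile = 1, frac = 1, seed = 1)
  # brute-force quartile assignment: the two smallest col_a values
  expect_equal(which(md$mask[, "b"]), setNames(7:8, c("P7", "P8")))
  expect_true(all(!md$mask[, "a"]))

  expect_equal(sum(ampute_mar(truth, "a", "b", 1, frac = 0, seed = 1)$mask), 0)
  expect_error(ampute_mar(truth, "a", "a", 1), "differ")
})

test_that("MAR masks are confined to eligible rows of col_b", {
  truth <- gaussian_truth(400, 6, seed = 33)
  md <- ampute_mar(truth, "V2", "V5", quartile = 3, frac = 0.5, seed = 5)
  eligible <- ehrmiss:::quartile_of(truth[, "V2"]) == 3
  expect_true(all(md$mask[!eligible, ] == FALSE))
  expect_true(all(md$mask[, setdiff(colnames(truth), "V5")] == FALSE))
})

test_that("the MAR grid has V*(V-1)*4 cells", {
  expect_length(mar_grid(gaussian_truth(20, 2, seed = 34), seed = 1), 8)
  expect_message(g1 <- mar_grid(gaussian_truth(20, 1, seed = 34), seed = 1),
                 "empty")
  expect_length(g1, 0)
})

test_that("MNAR amputation removes values from their own quartile", {
  x <- c(5, 2, 8, 1, 7, 3, 6, 4)
  truth <- cbind(v = x, w = rnorm(8))
  rownames(truth) <- paste0("P", 1:8)
  md <- ampute_mnar(truth, "v", quartile = 2, frac = 1, seed = 1)
  # brute force: ranks 3 and 4 of v (values 3 and 4)
  expect_setequal(md$truth[md$mask[, "v"], "v"], c(3, 4))

  md4 <- ampute_mnar(truth, "v", quartile = 4, frac = 1, seed = 1)
  expect_setequal(md4$truth[md4$mask[, "v"], "v"], c(7, 8))

  big <- gaussian_truth(500, 3, seed = 35)
  mdq <- ampute_mnar(big, "V1", quartile = 3, frac = 0.5, seed = 2)
  qs <- quantile(big[, "V1"], c(0.5, 0.75))
  removed <- big[mdq$mask[, "V1"], "V1"]
  expect_true(all(removed > qs[1] & removed <= qs[2]))
})

test_that("the MNAR grid has V*4 cells", {
  expect_length(mnar_grid(gaussian_truth(20, 3, seed = 36), seed = 1), 12)
  expect_length(mnar_grid(gaussian_truth(20, 1, seed = 36), seed = 1), 4)
})

test_that("realistic amputation copies the matched neighbour's pattern", {
  pop_m <- matrix(c(1, NA, 2,
                    NA, 5, 6,
                    7, 8, NA), 3, 3, byrow = TRUE,
                  dimnames = list(c("Q1", "Q2", "Q3"), c("a", "b", "c")))
  pop_d <- demo_table(c("Q1", "Q2", "Q3"), "F", c(30, 50, 70), c(25, 30, 35))
  cc_m <- matrix(rnorm(6), 2, 3, dimnames = list(c("K1", "K2"), c("a", "b", "c")))
  cc_d <- demo_table(c("K1", "K2"), "F", c(31, 69), c(25, 35))
  md <- ampute_realistic(lab_matrix(cc_m), cc_d, lab_matrix(pop_m), pop_d)
  # K1 matches Q1 (nearest on age/bmi), K2 matches Q3; copy their NA patterns.
  expect_equal(unname(md$mask["K1", ]), c(FALSE, TRUE, FALSE))
  expect_equal(unname(md$mask["K2", ]), c(FALSE, FALSE, TRUE))
})

test_that("a fully observed population leaves the mask empty", {
  pop_m <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("Q", 1:10), c("a", "b", "c")))
  pop_d <- demo_table(paste0("Q", 1:10), rep(c("F", "M"), 5),
                      runif(10, 20, 80), runif(10, 20, 40))
  cc_m <- pop_m[1:4, ]
  rownames(cc_m) <- paste0("K", 1:4)
  cc_d <- pop_d[1:4, ]
  cc_d$patient_id <- paste0("K", 1:4)
  md <- ampute_realistic(lab_matrix(cc_m), cc_d, lab_matrix(pop_m), pop_d)
  expect_equal(sum(md$mask), 0)
})

test_that("realistic per-variable missingness tracks the population's rates", {
  set.seed(38)
  n <- 600; V <- 28
  vars <- paste0("L", seq_len(V))
  rates <- seq(0.05, 0.6, length.out = V)
  pop_m <- matrix(rnorm(n * V), n, V, dimnames = list(sprintf("Q%04d", 1:n), vars))
  for (j in seq_len(V)) pop_m[runif(n) < rates[j], j] <- NA
  pop_d <- demo_table(rownames(pop_m), sample(c("F", "M"), n, TRUE),
                      runif(n, 20, 85), runif(n, 18, 45))
  cc_m <- matrix(rnorm(200 * V), 200, V, dimnames = list(sprintf("K%04d", 1:200), vars))
  cc_d <- demo_table(rownames(cc_m), sample(c("F", "M"), 200, TRUE),
                     runif(200, 20, 85), runif(200, 18, 45))
  md <- ampute_realistic(lab_matrix(cc_m), cc_d, lab_matrix(pop_m), pop_d)
  got <- colMeans(md$mask)
  expect_gt(cor(got, rates, method = "spearman"), 0.9)
})

test_that("unmasking reproduces the truth exactly for every mechanism", {
  truth <- gaussian_truth(60, 5, seed = 39)
  mds <- list(ampute_mcar(truth, 0.3, 1),
              ampute_mar(truth, "V1", "V2", 2, 0.5, 1),
              ampute_mnar(truth, "V3", 4, 0.5, 1))
  for (md in mds) {
    mv <- masked_values(md)
    expect_true(all(is.na(mv[md$mask])))
    mv[md$mask] <- md$truth[md$mask]
    expect_identical(mv, md$truth)
  }
})
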