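# Synthetic EHR generator: reproducibility, correlation recovery, and the
# observation (missingness) model.

test_that("identical seed and config give bitwise-identical tables", {
  cfg <- synth_config(n_patients = 80, seed = 11)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a$demographics, b$demographics)
  expect_identical(a$events, b$events)
  expect_identical(a$truth, b$truth)
})

test_that("zero patients yield empty tables without failure", {
  pop <- generate_population(synth_config(n_patients = 0, seed = 1))
  expect_equal(nrow(pop$demographics), 0)
  expect_equal(nrow(pop$events), 0)
  expect_equal(ncol(pop$truth), 28)
})

test_that("non-positive-definite correlation spec fails at construction", {
  expect_error(synth_config(within_panel_cor = -0.9, seed = 1),
               "positive definite")
})

test_that("within-panel latent correlation is recovered from the draws", {
  pm <- data.frame(loinc = paste0("L", 1:5), panel = "one",
                   stringsAsFactors = FALSE)
  cfg <- synth_config(n_patients = 5000, panel_map = pm,
                      within_panel_cor = 0.7, cross_panel_cor = 0,
                      records_per_patient = 1, seed = 21)
  pop <- generate_population(cfg)
  cors <- cor(pop$latent)
  off <- cors[upper.tri(cors)]
  expect_true(all(abs(off - 0.7) < 0.05))
})

test_that("uncorrelated config gives near-zero empirical correlations", {
  pm <- data.frame(loinc = paste0("L", 1:4), panel = "one",
                   stringsAsFactors = FALSE)
  cfg <- synth_config(n_patients = 3000, panel_map = pm,
                      within_panel_cor = 0, cross_panel_cor = 0,
                      marginal_lambda = 1, seed = 5)
  pop <- generate_population(cfg)
  cors <- cor(pop$truth)
  expect_true(max(abs(cors[upper.tri(cors)])) < 0.06)
})

test_that("marginals are positive under log and power transforms", {
  cfg <- synth_config(n_patients = 500, marginal_lambda = c(0, 0.3, 0.5),
                      seed = 2)
  pop <- generate_population(cfg)
  expect_true(all(pop$truth > 0))
  expect_true(all(pop$events$value > 0))
})

test_that("demographic invariants hold", {
  pop <- generate_population(synth_config(n_patients = 400, death_fraction = 0.3,
                                          seed = 13))
  d <- pop$demographics
  expect_false(anyDuplicated(d$patient_id) > 0)
  expect_true(all(d$bmi > 0))
  has_death <- !is.na(d$death_date)
  expect_gt(sum(has_death), 0)
  expect_true(all(d$death_date[has_death] >= d$birth_date[has_death]))
})

test_that("ground-truth mask reflects the generating observation model", {
  # All observed -> all-true mask.
  cfg_all <- synth_config(n_patients = 60, seed = 3,
                          obs_model = data.frame(panel = c("cbc", "chemistry", "lipids"),
                                                 intercept = 30))
  pop <- generate_population(cfg_all)
  mask <- ground_truth_mask(pop$events, pop$demographics,
                            variables = colnames(pop$truth))
  expect_true(all(mask))

  # Lipid panel never ordered -> lipid columns all-false.
  cfg_nolip <- synth_config(n_patients = 60, seed = 3,
                            obs_model = data.frame(panel = c("cbc", "chemistry", "lipids"),
                                                   intercept = c(30, 30, -30)))
  pop2 <- generate_population(cfg_nolip)
  mask2 <- ground_truth_mask(pop2$events, pop2$demographics,
                             variables = colnames(pop2$truth))
  lip <- cfg_nolip$panel_map$loinc[cfg_nolip$panel_map$panel == "lipids"]
  expect_true(all(!mask2[, lip]))
  expect_true(all(mask2[, setdiff(colnames(mask2), lip)]))
})

test_that("mask frequency matches the logistic observation model", {
  # Oracle: the mean of the logistic probabilities recomputed from the
  # demographics and the configured coefficients.
  cfg <- synth_config(n_patients = 4000, seed = 17,
                      obs_model = data.frame(panel = c("cbc", "chemistry", "lipids"),
                                             intercept = c(1, 0.5, -0.5),
                                             age = c(0.8, 0, 1),
                                             sex = c(0, 0.5, 0),
                                             bmi = c(0, 0, 0.7)))
  pop <- generate_population(cfg)
  d <- pop$demographics
  age_std <- (d$age - mean(d$age)) / sd(d$age)
  bmi_std <- (d$bmi - mean(d$bmi)) / sd(d$bmi)
  sexn <- as.numeric(d$sex == "M")
  for (k in seq_len(nrow(cfg$obs_model))) {
    om <- cfg$obs_model[k, ]
    p_exp <- mean(plogis(om$intercept + om$age * age_std + om$sex * sexn +
                           om$bmi * bmi_std))
    vars_k <- cfg$panel_map$loinc[cfg$panel_map$panel == om$panel]
    p_obs <- mean(pop$obs_mask[, vars_k[1]])
    half_ci <- qnorm(0.995) * sqrt(p_exp * (1 - p_exp) / nrow(d))
    expect_lt(abs(p_obs - p_exp), half_ci + 1e-12)
  }
})

test_that("MCAR-style generation is unpredictable, value-driven MNAR less than covariate MAR", {
  skip_if_not_installed("ranger")
  # Covariates shift the lab means so covariate-driven (MAR) missingness is
  # visible in the other observed labs.
  eff <- matrix(0, 28, 3)
  eff[, 1] <- 0.6  # age effect on every variable's latent mean
  cfg_mcar <- synth_config(n_patients = 2500, seed = 31,
                           covariate_effects = eff,
                           obs_model = data.frame(panel = c("cbc", "chemistry", "lipids"),
                                                  intercept = c(4, 4, 1)))
  pop <- generate_population(cfg_mcar)
  m <- population_matrix(pop, apply_mask = TRUE)
  pp <- predict_presence(m, "2093-3", folds = 5, seed = 1)
  expect_gt(pp$mean_auroc, 0.4)
  expect_lt(pp$mean_auroc, 0.6)

  cfg_mar <- synth_config(n_patients = 2500, seed = 31,
                          covariate_effects = eff,
                          obs_model = data.frame(panel = c("cbc", "chemistry", "lipids"),
                                                 intercept = c(4, 4, 0),
                                                 age = c(0, 0, 3)))
  pop_mar <- generate_population(cfg_mar)
  m_mar <- population_matrix(pop_mar, apply_mask = TRUE)
  pp_mar <- predict_presence(m_mar, "2093-3", folds = 5, seed = 1)
  expect_gt(pp_mar$mean_auroc, pp$mean_auroc + 0.1)
})
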