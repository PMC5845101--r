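# Synthetic EHR-like population generator.
#
# Latent model: a Gaussian copula. Each patient draws a multivariate-normal
# latent vector with a block (panel) correlation structure; covariates shift
# the latent means; a monotone inverse Box-Cox map produces skewed positive
# marginals. Observation of each panel is decided by a logistic model on
# age/sex/BMI (the MAR channel) and optionally on the panel's own latent
# values (the MNAR channel). Dated longitudinal events are scattered around a
# patient-specific anchor date.

#' Configuration for the synthetic EHR generator
#'
#' @param n_patients Number of patients (may be 0 for empty output).
#' @param panel_map Data.frame with columns `loinc` and `panel` defining the
#'   variables and their panel grouping. Default: the 28-variable map of
#'   [default_panel_map()].
#' @param within_panel_cor Latent correlation between variables of the same
#'   panel; a single number or a named vector (one entry per panel).
#' @param cross_panel_cor Latent correlation between variables of different
#'   panels, in `[0, 1)`.
#' @param marginal_lambda Inverse Box-Cox exponent of each variable's marginal
#'   (single number or per-variable vector). `0` gives lognormal marginals,
#'   `1` a location-shifted normal; smaller values are more right-skewed.
#' @param latent_location Location added to the latent scale before the
#'   marginal transform so that the transform is defined and positive.
#' @param covariate_effects Numeric matrix (variables x 3, columns
#'   `age`, `sex`, `bmi`) of effects of the standardized covariates on each
#'   variable's latent mean. Default all zero.
#' @param obs_model Data.frame (one row per panel, rownames or column `panel`)
#'   with columns `intercept`, `age`, `sex`, `bmi`, `value`: coefficients of a
#'   logistic model for the probability that a patient's panel is observed.
#'   `age`/`sex`/`bmi` act on standardized covariates (MAR channel); `value`
#'   multiplies the panel's mean latent value (MNAR channel). Default:
#'   intercept 4 (~98% observed), all slopes 0.
#' @param records_per_patient Mean number of dated events per observed
#'   (patient, variable) cell; each cell gets at least one event.
#' @param event_noise_sd Within-patient measurement noise on the latent scale.
#' @param cell_dropout Probability that an individual cell of an observed
#'   panel is nonetheless unrecorded (cell-level noise on top of panel-level
#'   ordering).
#' @param death_fraction Fraction of patients with a recorded death date.
#' @param seed Integer seed; identical config and seed give bitwise-identical
#'   output.
#' @return A `synth_config` list, validated (positive-definite implied latent
#'   correlation, probabilities in range).
#' @export
#' @examples
#' cfg <- synth_config(n_patients = 100, seed = 7)
synth_config <- function(n_patients = 1000,
                         panel_map = default_panel_map(),
                         within_panel_cor = 0.5,
                         cross_panel_cor = 0.2,
                         marginal_lambda = 0.5,
                         latent_location = 5,
                         covariate_effects = NULL,
                         obs_model = NULL,
                         records_per_patient = 3,
                         event_noise_sd = 0.05,
                         cell_dropout = 0,
                         death_fraction = 0.05,
                         seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 0)
    stop("`n_patients` must be a non-negative count", call. = FALSE)
  panel_map <- check_panel_map(panel_map, panel_map$loinc)
  panels <- unique(panel_map$panel)
  vars <- panel_map$loinc
  V <- length(vars)

  if (is.null(names(within_panel_cor)))
    within_panel_cor <- stats::setNames(rep_len(within_panel_cor, length(panels)), panels)
  if (!all(panels %in% names(within_panel_cor)))
    stop("`within_panel_cor` must name every panel", call. = FALSE)
  stopifnot_prob(cross_panel_cor + 1e-12, "cross_panel_cor", open = FALSE)
  if (cross_panel_cor >= 1) stop("`cross_panel_cor` must be < 1", call. = FALSE)
  stopifnot_prob(death_fraction, "death_fraction", open = FALSE)
  stopifnot_prob(cell_dropout, "cell_dropout", open = FALSE)
  if (records_per_patient < 1)
    stop("`records_per_patient` must be >= 1", call. = FALSE)

  marginal_lambda <- rep_len(marginal_lambda, V)

  if (is.null(covariate_effects)) {
    covariate_effects <- matrix(0, V, 3, dimnames = list(vars, c("age", "sex", "bmi")))
  } else {
    covariate_effects <- as.matrix(covariate_effects)
    if (nrow(covariate_effects) != V || ncol(covariate_effects) != 3)
      stop("`covariate_effects` must be a ", V, " x 3 matrix (age, sex, bmi)",
           call. = FALSE)
    colnames(covariate_effects) <- c("age", "sex", "bmi")
    rownames(covariate_effects) <- vars
  }

  if (is.null(obs_model)) {
    obs_model <- data.frame(panel = panels, intercept = 4, age = 0, sex = 0,
                            bmi = 0, value = 0, stringsAsFactors = FALSE)
  } else {
    obs_model <- as.data.frame(obs_model)
    if (!"panel" %in% names(obs_model)) obs_model$panel <- rownames(obs_model)
    need <- c("intercept", "age", "sex", "bmi", "value")
    for (cc in setdiff(need, names(obs_model))) obs_model[[cc]] <- 0
    if (!all(panels %in% obs_model$panel))
      stop("`obs_model` must have one row per panel", call. = FALSE)
    obs_model <- obs_model[match(panels, obs_model$panel),
                           c("panel", need)]
  }

  # Implied latent correlation matrix; fail at construction if not PD.
  sigma <- build_block_correlation(panel_map, within_panel_cor, cross_panel_cor)
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10)
    stop("implied latent correlation matrix is not positive definite ",
         "(smallest eigenvalue ", signif(ev, 3), ")", call. = FALSE)

  structure(list(n_patients = as.integer(n_patients), panel_map = panel_map,
                 within_panel_cor = within_panel_cor,
                 cross_panel_cor = cross_panel_cor,
                 marginal_lambda = marginal_lambda,
                 latent_location = latent_location,
                 covariate_effects = covariate_effects, obs_model = obs_model,
                 records_per_patient = records_per_patient,
                 event_noise_sd = event_noise_sd, cell_dropout = cell_dropout,
                 death_fraction = death_fraction, seed = as.integer(seed),
                 sigma = sigma),
            class = "synth_config")
}

build_block_correlation <- function(panel_map, within, cross) {
  vars <- panel_map$loinc
  V <- length(vars)
  sigma <- matrix(cross, V, V, dimnames = list(vars, vars))
  for (p in unique(panel_map$panel)) {
    idx <- which(panel_map$panel == p)
    sigma[idx, idx] <- within[[p]]
  }
  diag(sigma) <- 1
  sigma
}

# Monotone inverse Box-Cox: y on the latent (normalized) scale to a positive
# observed scale. lambda = 0 -> exp; otherwise (1 + lambda*y)^(1/lambda),
# clamped away from the boundary of its support.
inv_boxcox <- function(y, lambda) {
  if (abs(lambda) < 1e-12) return(exp(y))
  (pmax(1 + lambda * y, 1e-8))^(1 / lambda)
}

boxcox_transform <- function(x, lambda) {
  if (abs(lambda) < 1e-12) return(log(x))
  (x^lambda - 1) / lambda
}

#' Generate a synthetic EHR-like population
#'
#' Draws demographics (sex, birth date, optional death date, BMI), latent
#' correlated laboratory values, panel-level observation indicators, and
#' dated longitudinal laboratory events according to a [synth_config()].
#'
#' @param config A [synth_config()].
#' @return An object of class `synth_population`: a list with
#'   `demographics` (data.frame: `patient_id`, `sex`, `birth_date`,
#'   `death_date`, `bmi`, `age`), `events` (data.frame: `patient_id`,
#'   `loinc`, `date`, `value`), `truth` (complete patient x variable matrix
#'   of per-patient underlying values on the observed scale), `latent` (the
#'   multivariate-normal draws before the marginal transform), `obs_mask`
#'   (logical matrix: which cells were generated as observed), `obs_prob`
#'   (the logistic observation probabilities per patient x panel) and
#'   `config`.
#' @export
#' @examples
#' pop <- generate_population(synth_config(n_patients = 50, seed = 1))
#' head(pop$events)
generate_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_patients
  pm <- config$panel_map
  vars <- pm$loinc
  panels <- unique(pm$panel)
  V <- length(vars)
  epoch <- as.Date("2000-01-01")

  if (n == 0) {
    demo <- data.frame(patient_id = character(0), sex = character(0),
                       birth_date = as.Date(character(0)),
                       death_date = as.Date(character(0)),
                       bmi = numeric(0), age = numeric(0),
                       stringsAsFactors = FALSE)
    ev <- data.frame(patient_id = character(0), loinc = character(0),
                     date = as.Date(character(0)), value = numeric(0),
                     stringsAsFactors = FALSE)
    empty <- matrix(numeric(0), 0, V, dimnames = list(NULL, vars))
    return(structure(list(demographics = demo, events = ev, truth = empty,
                          latent = empty, obs_mask = empty > 0,
                          obs_prob = matrix(numeric(0), 0, length(panels),
                                            dimnames = list(NULL, panels)),
                          config = config),
                     class = "synth_population"))
  }

  ids <- sprintf("P%06d", seq_len(n))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- stats::runif(n, 20, 88)
  bmi <- stats::rlnorm(n, log(27), 0.17)
  anchor_offset <- sample.int(6000L, n, replace = TRUE)  # days from epoch
  anchor <- epoch + anchor_offset
  birth_date <- anchor - round(age * 365.25)
  death_date <- as.Date(rep(NA_integer_, n), origin = epoch)
  dead <- stats::runif(n) < config$death_fraction
  death_date[dead] <- anchor[dead] + sample(200:4000, sum(dead), replace = TRUE)

  age_std <- zscale(age)
  bmi_std <- zscale(bmi)
  sex_num <- as.numeric(sex == "M")

  # Latent multivariate normal with the block correlation structure.
  z <- matrix(stats::rnorm(n * V), n, V) %*% chol(config$sigma)
  latent <- z + cbind(age_std, sex_num, bmi_std) %*% t(config$covariate_effects)
  dimnames(latent) <- list(ids, vars)

  truth <- latent
  for (j in seq_len(V))
    truth[, j] <- inv_boxcox(latent[, j] + config$latent_location,
                             config$marginal_lambda[j])

  # Panel-level observation: logistic on standardized covariates (MAR) and,
  # optionally, on the panel's mean latent value (MNAR).
  obs_prob <- matrix(NA_real_, n, length(panels), dimnames = list(ids, panels))
  obs_panel <- matrix(NA, n, length(panels), dimnames = list(ids, panels))
  for (k in seq_along(panels)) {
    om <- config$obs_model[k, ]
    idx <- which(pm$panel == panels[k])
    panel_value <- rowMeans(latent[, idx, drop = FALSE])
    eta <- om$intercept + om$age * age_std + om$sex * sex_num +
      om$bmi * bmi_std + om$value * panel_value
    obs_prob[, k] <- stats::plogis(eta)
    obs_panel[, k] <- stats::runif(n) < obs_prob[, k]
  }
  obs_mask <- obs_panel[, match(pm$panel, panels), drop = FALSE]
  dimnames(obs_mask) <- list(ids, vars)
  if (config$cell_dropout > 0)
    obs_mask <- obs_mask & (matrix(stats::runif(n * V), n, V) >= config$cell_dropout)

  # Longitudinal events for every observed cell.
  cells <- which(obs_mask)
  n_rec <- 1L + stats::rpois(length(cells), config$records_per_patient - 1)
  cell_rep <- rep(cells, n_rec)
  row_i <- ((cell_rep - 1L) %% n) + 1L
  col_j <- ((cell_rep - 1L) %/% n) + 1L
  noise <- stats::rnorm(length(cell_rep), 0, config$event_noise_sd)
  ev_latent <- latent[cbind(row_i, col_j)] + config$latent_location + noise
  ev_value <- numeric(length(cell_rep))
  for (j in unique(col_j)) {
    sel <- col_j == j
    ev_value[sel] <- inv_boxcox(ev_latent[sel], config$marginal_lambda[j])
  }
  ev_date <- anchor[row_i] + round(stats::rnorm(length(cell_rep), 0, 180))
  events <- data.frame(patient_id = ids[row_i], loinc = vars[col_j],
                       date = ev_date, value = ev_value,
                       stringsAsFactors = FALSE)
  events <- events[order(events$patient_id, events$loinc, events$date), ]
  rownames(events) <- NULL

  demo <- data.frame(patient_id = ids, sex = sex, birth_date = birth_date,
                     death_date = death_date, bmi = bmi, age = age,
                     stringsAsFactors = FALSE)

  structure(list(demographics = demo, events = events, truth = truth,
                 latent = latent, obs_mask = obs_mask, obs_prob = obs_prob,
                 config = config),
            class = "synth_population")
}

#' @export
print.synth_population <- function(x, ...) {
  cat("<synth_population> ", nrow(x$demographics), " patients, ",
      ncol(x$truth), " variables, ", nrow(x$events), " events; ",
      sprintf("%.1f%%", 100 * mean(!x$obs_mask)), " cells unobserved\n",
      sep = "")
  invisible(x)
}

#' Wide matrix of a synthetic population's underlying values
#'
#' @param pop A `synth_population`.
#' @param apply_mask If `TRUE`, cells generated as unobserved are set `NA`
#'   (the matrix a perfect preprocessing of the events would recover); if
#'   `FALSE` the complete ground-truth matrix is returned.
#' @return A [lab_matrix()].
#' @export
population_matrix <- function(pop, apply_mask = FALSE) {
  stopifnot(inherits(pop, "synth_population"))
  v <- pop$truth
  if (apply_mask) v[!pop$obs_mask] <- NA_real_
  lab_matrix(v, panel_map = pop$config$panel_map)
}

#' Ground-truth observation mask from generated events
#'
#' Recomputes, from the long event table, which (patient, variable) pairs
#' carry at least one record. Used as labels when validating missingness
#' diagnostics against the generator's known observation model.
#'
#' @param events Long event table (`patient_id`, `loinc`, `date`, `value`).
#' @param demographics Demographics table defining the patient universe
#'   (patients with no events appear as all-`FALSE` rows).
#' @param variables Variable universe; defaults to the codes seen in `events`.
#' @return Logical patient x variable matrix, `TRUE` where observed.
#' @export
ground_truth_mask <- function(events, demographics,
                              variables = sort(unique(events$loinc))) {
  ids <- demographics$patient_id
  m <- matrix(FALSE, length(ids), length(variables),
              dimnames = list(ids, variables))
  keep <- events$loinc %in% variables
  if (any(keep))
    m[cbind(match(events$patient_id[keep], ids),
            match(events$loinc[keep], variables))] <- TRUE
  m
}
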