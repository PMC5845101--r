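# Complete-case extraction and representative covariate matching.

#' Extract complete cases for a set of variables
#'
#' @param x A [lab_matrix()] or matrix.
#' @param variables Variable subset defining completeness; default all
#'   columns. An empty set keeps every row (vacuous completeness).
#' @return A [lab_matrix()] restricted to the complete rows and the given
#'   variables.
#' @export
extract_complete_cases <- function(x, variables = NULL) {
  pm <- if (inherits(x, "lab_matrix")) x$panel_map else NULL
  v <- lab_values(x)
  if (is.null(variables)) variables <- colnames(v)
  if (!all(variables %in% colnames(v)))
    stop("unknown variables: ",
         paste(setdiff(variables, colnames(v)), collapse = ", "), call. = FALSE)
  sub <- v[, variables, drop = FALSE]
  keep <- if (length(variables)) rowSums(is.na(sub)) == 0 else rep(TRUE, nrow(v))
  if (!any(keep)) message("no complete cases for the requested variable set")
  if (!is.null(pm)) pm <- pm[pm$loinc %in% variables, , drop = FALSE]
  if (!length(variables)) pm <- NULL
  lab_matrix(sub[keep, , drop = FALSE], panel_map = pm)
}

# Sex-exact nearest neighbour on standardized (age, bmi). Candidates are
# scanned per sex; ties broken by lowest patient id. Age and BMI are Z-scored
# on the reference population so neither covariate dominates the distance.
nn_match <- function(query, candidates, ref, exclude_self = FALSE) {
  q_age <- zscale(query$age, ref$age)
  q_bmi <- zscale(query$bmi, ref$bmi)
  c_age <- zscale(candidates$age, ref$age)
  c_bmi <- zscale(candidates$bmi, ref$bmi)
  match_id <- character(nrow(query))
  dist <- numeric(nrow(query))
  for (s in unique(query$sex)) {
    qi <- which(query$sex == s)
    ci <- which(candidates$sex == s)
    if (!length(ci))
      stop("no candidate of sex '", s, "' available for matching", call. = FALSE)
    ci <- ci[order(candidates$patient_id[ci])]  # tie -> lowest id
    d2 <- outer(q_age[qi], c_age[ci], "-")^2 + outer(q_bmi[qi], c_bmi[ci], "-")^2
    if (exclude_self) {
      self <- outer(query$patient_id[qi], candidates$patient_id[ci], "==")
      if (any(rowSums(!self) == 0))
        stop("a patient has no same-sex non-self candidate", call. = FALSE)
      d2[self] <- Inf
    }
    best <- max.col(-d2, ties.method = "first")
    match_id[qi] <- candidates$patient_id[ci[best]]
    dist[qi] <- sqrt(d2[cbind(seq_along(qi), best)])
  }
  data.frame(patient_id = query$patient_id, match_id = match_id,
             distance = dist, stringsAsFactors = FALSE)
}

#' Match a random population sample to its most similar complete cases
#'
#' Samples `n` patients from the population without replacement and matches
#' each to the complete case of identical sex with minimal euclidean distance
#' on age and BMI (both Z-scored on the population). Complete cases may serve
#' as the match for several sampled patients (matching with replacement);
#' distance ties are broken by lowest patient id.
#'
#' @param population Demographics data.frame (`patient_id`, `sex`, `age`,
#'   `bmi`) of the whole population.
#' @param complete_cases Demographics of the complete-case pool.
#' @param n Sample size (`<=` population size).
#' @param seed Integer seed for the sampling step.
#' @return A data.frame (`patient_id`, `match_id`, `distance`), one row per
#'   sampled patient.
#' @export
match_representative_sample <- function(population, complete_cases, n, seed = 1) {
  if (n > nrow(population))
    stop("`n` exceeds the population size", call. = FALSE)
  set.seed(seed)
  sampled <- population[sample.int(nrow(population), n), , drop = FALSE]
  res <- nn_match(sampled, complete_cases, ref = population)
  rownames(res) <- NULL
  res
}
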