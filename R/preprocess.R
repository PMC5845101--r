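# Long events -> one Box-Cox + Z-transformed value per patient per variable.

#' Filter laboratory events by age, proximity to death, and variable prevalence
#'
#' Retains events recorded between the patient's 18th and 90th birthdays
#' (ages computed in exact days / 365.25), drops events dated within 365 days
#' before a recorded death date (and any event after death), and drops
#' variables observed in fewer than `min_prevalence` of all patients.
#'
#' @param events Long event table (`patient_id`, `loinc`, `date`, `value`).
#' @param demographics Demographics covering every patient in `events`
#'   (`patient_id`, `birth_date`, optional `death_date`).
#' @param min_prevalence Minimum fraction of patients (of
#'   `nrow(demographics)`) with at least one retained result for a variable
#'   to be kept. Default 0.005.
#' @return The filtered event table. Retained rows are unmodified.
#' @export
filter_records <- function(events, demographics, min_prevalence = 0.005) {
  stopifnot_prob(min_prevalence + 1e-12, "min_prevalence", open = FALSE)
  idx <- match(events$patient_id, demographics$patient_id)
  if (anyNA(idx)) {
    bad <- unique(events$patient_id[is.na(idx)])
    stop("events reference patients absent from demographics: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  age_days <- as.numeric(as.Date(events$date) - as.Date(demographics$birth_date[idx]))
  age <- age_days / 365.25
  keep <- age >= 18 & age <= 90
  death <- as.Date(demographics$death_date[idx])
  near_death <- !is.na(death) & as.numeric(as.Date(events$date)) >= (as.numeric(death) - 365)
  keep <- keep & !near_death
  out <- events[keep, , drop = FALSE]

  if (min_prevalence > 0 && nrow(out)) {
    n_pat <- nrow(demographics)
    prev <- tapply(out$patient_id, out$loinc, function(p) length(unique(p))) / n_pat
    keep_vars <- names(prev)[prev >= min_prevalence]
    out <- out[out$loinc %in% keep_vars, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Aggregate events into a patient-by-variable matrix of windowed medians
#'
#' Per patient, computes the median event date (an even count of dates gives
#' the midpoint of the two central dates), drops events more than 5 years
#' (1826 days) from it, and sets each (patient, variable) cell to the median
#' of the remaining values. Pairs with no surviving event are missing.
#'
#' @param events Filtered long event table.
#' @param panel_map Optional panel map passed through to the [lab_matrix()].
#' @param window_days Half-width of the temporal window. Default 1826.
#' @return An untransformed [lab_matrix()].
#' @export
window_and_aggregate <- function(events, panel_map = NULL, window_days = 1826) {
  if (!nrow(events))
    return(lab_matrix(matrix(numeric(0), 0, 0), panel_map = NULL))
  d <- as.numeric(as.Date(events$date))
  med <- stats::ave(d, events$patient_id, FUN = stats::median)
  keep <- abs(d - med) <= window_days
  dropped_pat <- setdiff(unique(events$patient_id), unique(events$patient_id[keep]))
  if (length(dropped_pat))
    message(length(dropped_pat), " patient(s) had no event inside the ",
            "temporal window and were dropped")
  ev <- events[keep, , drop = FALSE]

  pats <- sort(unique(ev$patient_id))
  vars <- sort(unique(ev$loinc))
  agg <- stats::aggregate(value ~ patient_id + loinc, data = ev,
                          FUN = stats::median)
  m <- matrix(NA_real_, length(pats), length(vars),
              dimnames = list(pats, vars))
  m[cbind(match(agg$patient_id, pats), match(agg$loinc, vars))] <- agg$value
  if (!is.null(panel_map))
    panel_map <- panel_map[panel_map$loinc %in% vars, , drop = FALSE]
  lab_matrix(m, panel_map = panel_map)
}

# Profile maximum-likelihood Box-Cox exponent for a positive sample.
# Golden-section/parabolic search via stats::optimize on [-3, 3], tol 1e-4.
boxcox_lambda <- function(y, lower = -3, upper = 3, tol = 1e-4) {
  ly <- log(y)
  sly <- sum(ly)
  n <- length(y)
  ll <- function(l) {
    z <- if (abs(l) < 1e-12) ly else (y^l - 1) / l
    v <- mean((z - mean(z))^2)
    -n / 2 * log(v) + (l - 1) * sly
  }
  stats::optimize(ll, c(lower, upper), maximum = TRUE, tol = tol)$maximum
}

#' Box-Cox and Z-transform every variable of a laboratory matrix
#'
#' Per variable, on observed cells only: shifts the values by
#' `1e-6 - min` when the minimum is non-positive, chooses the Box-Cox
#' exponent by profile maximum likelihood over `[-3, 3]`, applies the power
#' transform, and standardizes to mean 0, sd 1. The parameters are stored on
#' the returned matrix so the transform can be inverted with
#' [invert_boxcox_z()].
#'
#' @param x A [lab_matrix()] (or plain matrix) of positive-scale values.
#' @return A `lab_matrix` of transformed values whose `transforms` element is
#'   a data.frame with columns `variable`, `shift`, `lambda`, `mean`, `sd`.
#' @export
boxcox_z <- function(x) {
  pm <- if (inherits(x, "lab_matrix")) x$panel_map else NULL
  v <- lab_values(x)
  out <- v
  params <- data.frame(variable = colnames(v), shift = NA_real_,
                       lambda = NA_real_, mean = NA_real_, sd = NA_real_,
                       stringsAsFactors = FALSE)
  for (j in seq_len(ncol(v))) {
    obs <- which(!is.na(v[, j]))
    y <- v[obs, j]
    if (length(unique(y)) < 2)
      stop("variable '", colnames(v)[j],
           "' is constant on observed cells (sd = 0)", call. = FALSE)
    shift <- if (min(y) <= 0) 1e-6 - min(y) else 0
    y <- y + shift
    lambda <- boxcox_lambda(y)
    z <- boxcox_transform(y, lambda)
    mu <- mean(z)
    sdev <- stats::sd(z)
    out[obs, j] <- (z - mu) / sdev
    params[j, -1] <- c(shift, lambda, mu, sdev)
  }
  lab_matrix(out, panel_map = pm, transforms = params)
}

#' Invert the Box-Cox + Z transform
#'
#' @param x Transformed `lab_matrix` or plain matrix.
#' @param params Transform record; defaults to the one attached to `x`.
#' @return A `lab_matrix` on the original scale.
#' @export
invert_boxcox_z <- function(x, params = NULL) {
  if (is.null(params)) {
    stopifnot(inherits(x, "lab_matrix"))
    params <- x$transforms
  }
  if (is.null(params)) stop("no transform parameters available", call. = FALSE)
  pm <- if (inherits(x, "lab_matrix")) x$panel_map else NULL
  v <- lab_values(x)
  stopifnot(identical(colnames(v), params$variable))
  for (j in seq_len(ncol(v))) {
    z <- v[, j] * params$sd[j] + params$mean[j]
    y <- if (abs(params$lambda[j]) < 1e-12) exp(z)
         else (params$lambda[j] * z + 1)^(1 / params$lambda[j])
    v[, j] <- y - params$shift[j]
  }
  lab_matrix(v, panel_map = pm)
}
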