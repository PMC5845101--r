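# Amputation: simulate missingness in complete data under four mechanisms,
# keeping the ground truth so imputations can be scored.

new_masked_dataset <- function(truth, mask, spec) {
  stopifnot(identical(dim(truth), dim(mask)))
  if (anyNA(truth)) stop("`truth` must be complete", call. = FALSE)
  structure(list(truth = truth, mask = mask, spec = spec),
            class = "masked_dataset")
}

check_complete_truth <- function(truth) {
  v <- lab_values(truth)
  if (anyNA(v)) stop("`truth` must be a complete matrix", call. = FALSE)
  v
}

#' Masked values of an amputed dataset
#'
#' @param x A `masked_dataset`.
#' @return The truth matrix with amputed cells set to `NA`.
#' @export
masked_values <- function(x) {
  stopifnot(inherits(x, "masked_dataset"))
  v <- x$truth
  v[x$mask] <- NA_real_
  v
}

#' @export
print.masked_dataset <- function(x, ...) {
  cat("<masked_dataset> ", x$spec$mechanism, ": ", nrow(x$truth), " x ",
      ncol(x$truth), ", ", sum(x$mask), " cells removed (",
      sprintf("%.1f%%", 100 * mean(x$mask)), ")\n", sep = "")
  invisible(x)
}

#' Ampute completely at random (MCAR)
#'
#' Each cell is removed independently with probability `p`.
#'
#' @param truth Complete matrix or [lab_matrix()].
#' @param p Missingness probability in `(0, 1)`.
#' @param seed Integer seed.
#' @return A `masked_dataset` (elements `truth`, `mask`, `spec`).
#' @export
ampute_mcar <- function(truth, p, seed = 1) {
  stopifnot_prob(p, "p", open = TRUE)
  v <- check_complete_truth(truth)
  set.seed(seed)
  mask <- matrix(stats::runif(length(v)) < p, nrow(v), ncol(v),
                 dimnames = dimnames(v))
  new_masked_dataset(v, mask, list(mechanism = "MCAR", p = p, seed = seed))
}

#' MCAR amputation grid
#'
#' One dataset per (missingness level, replicate); the defaults — five levels
#' from 10% to 50%, ten replicates each — yield 50 datasets.
#'
#' @param truth Complete matrix.
#' @param levels Missingness fractions.
#' @param reps Replicates per level.
#' @param seed Master seed; per-dataset seeds are derived by hashing the cell
#'   spec so the grid is order-independent.
#' @return Named list of `masked_dataset`s.
#' @export
mcar_grid <- function(truth, levels = seq(0.1, 0.5, by = 0.1), reps = 10,
                      seed = 1) {
  v <- check_complete_truth(truth)
  out <- list()
  for (p in levels) {
    for (r in seq_len(reps)) {
      md <- ampute_mcar(v, p, seed = derive_seed(seed, "mcar", p, r))
      md$spec$replicate <- r
      out[[sprintf("mcar_p%02.0f_r%02d", 100 * p, r)]] <- md
    }
  }
  out
}

#' Ampute at random (MAR)
#'
#' Rows whose `col_a` value lies in the stated quartile of `col_a`'s
#' empirical distribution lose their `col_b` cell independently with
#' probability `frac`. No other cell is touched; since `col_a` stays
#' observed, the missingness of `col_b` is fully explained by observed data.
#'
#' @param truth Complete matrix.
#' @param col_a,col_b Distinct variable names: the conditioning and the
#'   amputed column.
#' @param quartile Quartile of `col_a` (1-4) defining eligibility.
#' @param frac Removal probability among eligible cells (default 0.5).
#' @param seed Integer seed.
#' @return A `masked_dataset`.
#' @export
ampute_mar <- function(truth, col_a, col_b, quartile, frac = 0.5, seed = 1) {
  v <- check_complete_truth(truth)
  if (identical(col_a, col_b)) stop("`col_a` and `col_b` must differ", call. = FALSE)
  stopifnot(col_a %in% colnames(v), col_b %in% colnames(v),
            quartile %in% 1:4)
  stopifnot_prob(frac, "frac", open = FALSE)
  set.seed(seed)
  eligible <- quartile_of(v[, col_a]) == quartile
  mask <- matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v))
  mask[eligible, col_b] <- stats::runif(sum(eligible)) < frac
  new_masked_dataset(v, mask, list(mechanism = "MAR", col_a = col_a,
                                   col_b = col_b, quartile = quartile,
                                   frac = frac, seed = seed))
}

#' MAR amputation grid over all ordered column pairs and quartiles
#'
#' One dataset per ordered pair `(col_a, col_b)` with `col_a != col_b`, per
#' quartile: `V * (V - 1) * 4` datasets (3,024 at V = 28).
#'
#' @inheritParams ampute_mar
#' @param seed Master seed (per-dataset seeds derived by hashing the spec).
#' @return Named list of `masked_dataset`s (empty, with a message, at V < 2).
#' @export
mar_grid <- function(truth, frac = 0.5, seed = 1) {
  v <- check_complete_truth(truth)
  vars <- colnames(v)
  if (length(vars) < 2) {
    message("fewer than 2 variables: MAR grid is empty")
    return(list())
  }
  out <- list()
  for (a in vars) for (b in vars) {
    if (a == b) next
    for (q in 1:4) {
      out[[paste("mar", a, b, q, sep = "_")]] <-
        ampute_mar(v, a, b, q, frac, seed = derive_seed(seed, "mar", a, b, q))
    }
  }
  out
}

#' Ampute not at random (MNAR)
#'
#' Cells of `col` whose own value lies in the stated quartile are removed
#' independently with probability `frac`; missingness depends on the value
#' being removed, so it cannot be fully explained by the observed data.
#'
#' @param truth Complete matrix.
#' @param col Variable to ampute.
#' @param quartile Quartile of `col` (1-4).
#' @param frac Removal probability within the quartile (default 0.5).
#' @param seed Integer seed.
#' @return A `masked_dataset`.
#' @export
ampute_mnar <- function(truth, col, quartile, frac = 0.5, seed = 1) {
  v <- check_complete_truth(truth)
  stopifnot(col %in% colnames(v), quartile %in% 1:4)
  stopifnot_prob(frac, "frac", open = FALSE)
  set.seed(seed)
  eligible <- quartile_of(v[, col]) == quartile
  mask <- matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v))
  mask[eligible, col] <- stats::runif(sum(eligible)) < frac
  new_masked_dataset(v, mask, list(mechanism = "MNAR", col = col,
                                   quartile = quartile, frac = frac,
                                   seed = seed))
}

#' MNAR amputation grid over all columns and quartiles
#'
#' `V * 4` datasets (112 at V = 28).
#'
#' @inheritParams ampute_mnar
#' @param seed Master seed.
#' @return Named list of `masked_dataset`s.
#' @export
mnar_grid <- function(truth, frac = 0.5, seed = 1) {
  v <- check_complete_truth(truth)
  out <- list()
  for (col in colnames(v)) for (q in 1:4) {
    out[[paste("mnar", col, q, sep = "_")]] <-
      ampute_mnar(v, col, q, frac, seed = derive_seed(seed, "mnar", col, q))
  }
  out
}

#' Ampute by copying realistic missingness patterns
#'
#' Each complete-case patient is matched to their nearest neighbour in the
#' population (sex exact, euclidean distance on population-standardized age
#' and BMI, self-matches excluded, ties to lowest patient id) and inherits
#' that neighbour's missingness pattern: a cell is removed exactly when it is
#' absent in the matched patient.
#'
#' @param cc_matrix Complete-case [lab_matrix()] (complete in the shared
#'   variables).
#' @param cc_demographics Demographics of the complete cases (`patient_id`,
#'   `sex`, `age`, `bmi`).
#' @param pop_matrix Population [lab_matrix()] whose `NA` pattern is copied.
#' @param pop_demographics Population demographics.
#' @return A `masked_dataset` whose spec records each patient's match.
#' @export
ampute_realistic <- function(cc_matrix, cc_demographics, pop_matrix,
                             pop_demographics) {
  v <- check_complete_truth(cc_matrix)
  pv <- lab_values(pop_matrix)
  shared <- intersect(colnames(v), colnames(pv))
  if (!length(shared)) stop("no shared variables", call. = FALSE)
  v <- v[, shared, drop = FALSE]
  cc_demo <- cc_demographics[match(rownames(v), cc_demographics$patient_id), ]
  if (anyNA(cc_demo$patient_id))
    stop("cc_demographics must cover every complete-case patient", call. = FALSE)
  matches <- nn_match(cc_demo, pop_demographics, ref = pop_demographics,
                      exclude_self = TRUE)
  donor_rows <- match(matches$match_id, rownames(pv))
  mask <- is.na(pv[donor_rows, shared, drop = FALSE])
  dimnames(mask) <- dimnames(v)
  new_masked_dataset(v, mask, list(mechanism = "REALISTIC", matches = matches))
}
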