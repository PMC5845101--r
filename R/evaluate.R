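# Scoring imputations: masked-cell RMSE and multiple-imputation calibration.

#' Root mean square error over masked cells
#'
#' @param completed Completed matrix (or `completed_set`, scored copy by
#'   copy and averaged).
#' @param truth Ground-truth matrix of the same shape.
#' @param mask Logical matrix, `TRUE` at the cells to score.
#' @param scope `"overall"` (one number) or `"per_variable"` (named vector;
#'   variables with no masked cell are `NA`, i.e. undefined, not zero).
#' @return RMSE value(s).
#' @export
#' @examples
#' rmse_masked(matrix(c(2, 4)), matrix(c(1, 2)), matrix(c(TRUE, TRUE)))
rmse_masked <- function(completed, truth, mask,
                        scope = c("overall", "per_variable")) {
  scope <- match.arg(scope)
  if (inherits(completed, "completed_set")) {
    per <- vapply(completed$imputations, rmse_masked, truth = truth,
                  mask = mask, scope = "overall", numeric(1))
    if (scope == "overall") return(mean(per))
    pv <- matrix(sapply(completed$imputations, rmse_masked, truth = truth,
                        mask = mask, scope = "per_variable"),
                 nrow = ncol(lab_values(truth)),
                 dimnames = list(colnames(lab_values(truth)), NULL))
    return(rowMeans(pv))
  }
  a <- lab_values(completed)
  b <- lab_values(truth)
  stopifnot(identical(dim(a), dim(b)), identical(dim(a), dim(mask)))
  if (!any(mask)) stop("`mask` selects no cell", call. = FALSE)
  if (scope == "overall")
    return(sqrt(mean((a[mask] - b[mask])^2)))
  out <- vapply(seq_len(ncol(a)), function(j) {
    sel <- mask[, j]
    if (!any(sel)) return(NA_real_)
    sqrt(mean((a[sel, j] - b[sel, j])^2))
  }, numeric(1))
  stats::setNames(out, colnames(a))
}

#' Multiple-imputation calibration against withheld truth
#'
#' For each variable, `x` is the RMSE between the completed copies and the
#' truth (averaged over copies) and `y` the mean pairwise RMSE between
#' copies, both restricted to masked cells. Well-calibrated multiple
#' imputation has `x` close to `y` (points on the unity line); deterministic
#' methods have `y = 0` for every variable. The mean deviation from unity,
#' `MD = mean(x - y)` over variables, summarizes each method: 0 indicates
#' calibrated uncertainty, positive values under-dispersion or bias.
#'
#' @param cs A `completed_set` with `m >= 2` copies.
#' @param truth Ground-truth matrix.
#' @param mask Logical matrix of scored cells; defaults to the set's own
#'   imputation mask.
#' @return List with `table` (data.frame: `variable`, `x`, `y`) and `md`.
#' @export
mi_calibration <- function(cs, truth, mask = cs$mask) {
  stopifnot(inherits(cs, "completed_set"))
  if (cs$m < 2) stop("calibration requires m >= 2 imputations", call. = FALSE)
  imps <- cs$imputations
  V <- ncol(lab_values(truth))
  xm <- matrix(sapply(imps, rmse_masked, truth = truth, mask = mask,
                      scope = "per_variable"), nrow = V)
  x <- rowMeans(xm)
  pairs <- utils::combn(length(imps), 2)
  ym <- matrix(apply(pairs, 2, function(pr) {
    rmse_masked(imps[[pr[1]]], imps[[pr[2]]], mask, scope = "per_variable")
  }), nrow = V)
  y <- rowMeans(ym)
  tab <- data.frame(variable = colnames(lab_values(truth)), x = unname(x),
                    y = unname(y), stringsAsFactors = FALSE)
  list(table = tab, md = mean(tab$x - tab$y, na.rm = TRUE))
}

#' Benchmark imputation methods across amputed datasets
#'
#' Runs the cartesian product of masked datasets and methods, scoring each
#' cell by overall and per-variable RMSE and (at `m >= 2`) calibration. A
#' method failing on a dataset is recorded as failed and the run continues.
#'
#' @param datasets Named list of `masked_dataset`s (e.g. from [mcar_grid()]).
#' @param methods Character vector of method names accepted by [impute()].
#' @param m Copies per imputation (default 5).
#' @param seed Master seed; each (dataset, method) cell derives its own.
#' @param ... Further arguments passed to [impute()].
#' @return Tidy data.frame with one row per dataset x method x variable plus
#'   an aggregate row (`scope == "overall"`); columns `dataset`, `mechanism`,
#'   `method`, `scope`, `variable`, `rmse`, `between_rmse`, `failed`.
#' @export
benchmark_imputation <- function(datasets, methods, m = 5, seed = 1, ...) {
  if (is.null(names(datasets)))
    names(datasets) <- sprintf("dataset%03d", seq_along(datasets))
  rows <- list()
  for (dn in names(datasets)) {
    ds <- datasets[[dn]]
    for (meth in methods) {
      cell <- tryCatch({
        cs <- impute(ds, method = meth, m = m,
                     seed = derive_seed(seed, "bench", dn, meth), ...)
        pv <- rmse_masked(cs, ds$truth, ds$mask, scope = "per_variable")
        ov <- rmse_masked(cs, ds$truth, ds$mask, scope = "overall")
        if (m >= 2) {
          cal <- mi_calibration(cs, ds$truth, ds$mask)
          btw <- stats::setNames(cal$table$y, cal$table$variable)
        } else {
          btw <- stats::setNames(rep(NA_real_, length(pv)), names(pv))
        }
        data.frame(dataset = dn, mechanism = ds$spec$mechanism, method = meth,
                   scope = c("overall", rep("variable", length(pv))),
                   variable = c(NA_character_, names(pv)),
                   rmse = c(ov, unname(pv)),
                   between_rmse = c(mean(btw, na.rm = TRUE), unname(btw)),
                   failed = FALSE, stringsAsFactors = FALSE)
      }, error = function(e) {
        message("benchmark cell failed (", dn, ", ", meth, "): ",
                conditionMessage(e))
        data.frame(dataset = dn, mechanism = ds$spec$mechanism, method = meth,
                   scope = "overall", variable = NA_character_,
                   rmse = NA_real_, between_rmse = NA_real_, failed = TRUE,
                   stringsAsFactors = FALSE)
      })
      rows[[paste(dn, meth)]] <- cell
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
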