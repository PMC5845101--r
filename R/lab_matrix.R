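#' Patient-by-variable laboratory matrix
#'
#' The central wide container: one row per patient, one column per laboratory
#' variable, `NA` for missing cells, plus per-variable panel metadata and
#' (after [boxcox_z()]) the transform parameters needed to invert the
#' normalization.
#'
#' @param values Numeric matrix with patient ids as rownames and variable
#'   (LOINC) codes as colnames. `NA` marks a missing cell.
#' @param panel_map Optional data.frame with columns `loinc` and `panel`
#'   covering every column of `values`. When `NULL` all variables are placed
#'   in a single panel `"all"`.
#' @param transforms Optional per-variable transform record as returned by
#'   [boxcox_z()].
#' @return An object of class `lab_matrix` with elements `values`,
#'   `panel_map` and `transforms`.
#' @export
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("P", 1:3), c("a", "b")))
#' lab_matrix(m)
lab_matrix <- function(values, panel_map = NULL, transforms = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%06d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("V%03d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("patient ids (rownames) must be unique", call. = FALSE)
  if (any(is.infinite(values)))
    stop("`values` must not contain infinite cells", call. = FALSE)
  if (is.null(panel_map)) {
    panel_map <- data.frame(loinc = colnames(values),
                            panel = rep("all", ncol(values)),
                            stringsAsFactors = FALSE)
  } else {
    panel_map <- check_panel_map(panel_map, colnames(values))
  }
  structure(list(values = values, panel_map = panel_map,
                 transforms = transforms),
            class = "lab_matrix")
}

#' @export
dim.lab_matrix <- function(x) dim(x$values)

#' @export
as.matrix.lab_matrix <- function(x, ...) x$values

#' @export
print.lab_matrix <- function(x, ...) {
  v <- x$values
  cat("<lab_matrix> ", nrow(v), " patients x ", ncol(v), " variables; ",
      sum(is.na(v)), " missing cells (",
      sprintf("%.1f%%", 100 * mean(is.na(v))), ")\n", sep = "")
  cat("panels: ", paste(sprintf("%s (%d)", names(table(x$panel_map$panel)),
                                table(x$panel_map$panel)), collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$transforms)) cat("Box-Cox/Z transform parameters attached\n")
  invisible(x)
}

# Panel of each column, aligned with colnames(values).
panel_of <- function(x) {
  stopifnot(inherits(x, "lab_matrix"))
  x$panel_map$panel[match(colnames(x$values), x$panel_map$loinc)]
}
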