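# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a key
#'
#' Grid generators and pipeline stages draw many independent random streams
#' from one master seed. Sub-seeds are produced by a stable polynomial hash of
#' the master seed together with a descriptive key, so a grid is reproducible
#' and each of its cells is independent of the order in which cells are built.
#'
#' @param master Integer master seed.
#' @param ... Key components (coerced to character) identifying the stream.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "mcar", 0.3, 1)
derive_seed <- function(master, ...) {
  key <- paste(as.character(master),
               paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                            character(1)), collapse = "|"),
               sep = "|")
  h <- 17
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% 2147483629
  as.integer(h)
}

# Quartile membership with ties assigned to the lower quartile.
# Empirical type-7 quantiles at 0.25/0.5/0.75; intervals are left-open so a
# value equal to a cut point falls in the quartile below it.
quartile_of <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  findInterval(x, q, left.open = TRUE) + 1L
}

# Coerce the containers used across the package to a plain numeric matrix.
lab_values <- function(x) {
  if (inherits(x, "lab_matrix")) return(x$values)
  if (inherits(x, "masked_dataset")) return(masked_values(x))
  if (is.data.frame(x)) return(as.matrix(x))
  if (is.matrix(x)) return(x)
  stop("cannot interpret object of class '", paste(class(x), collapse = "/"),
       "' as a patient-by-variable matrix", call. = FALSE)
}

# Standardize a numeric vector using reference mean/sd (population scaling for
# matching); constant vectors map to zero rather than NaN.
zscale <- function(x, ref = x) {
  s <- stats::sd(ref)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(ref)) / s
}

stopifnot_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
  if (!ok) stop("`", name, "` must be a single number in ",
                if (open) "(0, 1)" else "[0, 1]", call. = FALSE)
  invisible(x)
}
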