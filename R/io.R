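# Delimited-text formats: comma-separated, header row, ISO-8601 dates, empty
# cell = missing, masks as 0/1. Writers emit a canonical form that
# round-trips byte-identically through the readers.

fmt_num <- function(x) ifelse(is.na(x), "", vapply(x, function(v)
  as.character(v), character(1)))

write_delim_lines <- function(fields_list, path) {
  lines <- vapply(fields_list, paste, character(1), collapse = ",")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

read_delim_raw <- function(path, required) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  unknown <- setdiff(names(df), required$all %||% required$cols)
  if (!is.null(required$cols)) {
    miss <- setdiff(required$cols, names(df))
    if (length(miss))
      stop(basename(path), ": missing column(s) ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  df
}

parse_date_col <- function(x, path, col) {
  ok <- x == "" | grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d <- as.Date(ifelse(x == "", NA, x), format = "%Y-%m-%d")
  bad <- which(!ok | (x != "" & is.na(d)))
  if (length(bad))
    stop(basename(path), " line ", bad[1] + 1, ": malformed date '",
         x[bad[1]], "' in column '", col, "'", call. = FALSE)
  d
}

parse_num_col <- function(x, path, col, allow_empty = FALSE) {
  v <- suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  bad <- which(x != "" & is.na(v))
  if (length(bad))
    stop(basename(path), " line ", bad[1] + 1, ": non-numeric value '",
         x[bad[1]], "' in column '", col, "'", call. = FALSE)
  if (!allow_empty && any(x == ""))
    stop(basename(path), " line ", which(x == "")[1] + 1,
         ": empty value in column '", col, "'", call. = FALSE)
  v
}

#' Read / write long-format laboratory events
#'
#' Columns `patient_id`, `loinc`, `date` (ISO-8601), `value`.
#'
#' @param path File path.
#' @return `read_long_events()`: a data.frame; `write_long_events()`: the
#'   path, invisibly.
#' @export
read_long_events <- function(path) {
  df <- read_delim_raw(path, list(cols = c("patient_id", "loinc", "date", "value")))
  data.frame(patient_id = df$patient_id, loinc = df$loinc,
             date = parse_date_col(df$date, path, "date"),
             value = parse_num_col(df$value, path, "value"),
             stringsAsFactors = FALSE)
}

#' @rdname read_long_events
#' @param events Event data.frame.
#' @export
write_long_events <- function(events, path) {
  header <- "patient_id,loinc,date,value"
  body <- paste(events$patient_id, events$loinc,
                format(as.Date(events$date), "%Y-%m-%d"),
                fmt_num(events$value), sep = ",")
  write_delim_lines(as.list(c(header, body)), path)
  invisible(path)
}

#' Read / write a demographics table
#'
#' Columns `patient_id`, `sex`, `birth_date`, `death_date` (empty when
#' absent), `bmi`, `age`.
#'
#' @param path File path.
#' @return `read_demographics()`: a data.frame; the writer returns the path.
#' @export
read_demographics <- function(path) {
  cols <- c("patient_id", "sex", "birth_date", "death_date", "bmi", "age")
  df <- read_delim_raw(path, list(cols = cols))
  if (anyDuplicated(df$patient_id))
    stop(basename(path), ": duplicated patient_id '",
         df$patient_id[anyDuplicated(df$patient_id)], "'", call. = FALSE)
  data.frame(patient_id = df$patient_id, sex = df$sex,
             birth_date = parse_date_col(df$birth_date, path, "birth_date"),
             death_date = parse_date_col(df$death_date, path, "death_date"),
             bmi = parse_num_col(df$bmi, path, "bmi"),
             age = parse_num_col(df$age, path, "age"),
             stringsAsFactors = FALSE)
}

#' @rdname read_demographics
#' @param demographics Demographics data.frame.
#' @export
write_demographics <- function(demographics, path) {
  d <- demographics
  header <- "patient_id,sex,birth_date,death_date,bmi,age"
  dd <- ifelse(is.na(d$death_date), "",
               format(as.Date(d$death_date), "%Y-%m-%d"))
  body <- paste(d$patient_id, d$sex, format(as.Date(d$birth_date), "%Y-%m-%d"),
                dd, fmt_num(d$bmi), fmt_num(d$age), sep = ",")
  write_delim_lines(as.list(c(header, body)), path)
  invisible(path)
}

#' Read / write a wide patient-by-variable matrix
#'
#' First column `patient_id`, one column per variable, empty cell = missing.
#'
#' @param path File path.
#' @return `read_wide_matrix()`: a [lab_matrix()] (the panel map, if wanted,
#'   is attached by the caller); the writer returns the path.
#' @export
read_wide_matrix <- function(path) {
  df <- read_delim_raw(path, list(cols = "patient_id"))
  dup <- which(duplicated(df$patient_id))
  if (length(dup))
    stop(basename(path), " line ", dup[1] + 1, ": duplicate patient_id '",
         df$patient_id[dup[1]], "'", call. = FALSE)
  vars <- setdiff(names(df), "patient_id")
  m <- matrix(NA_real_, nrow(df), length(vars),
              dimnames = list(df$patient_id, vars))
  for (j in seq_along(vars))
    m[, j] <- parse_num_col(df[[vars[j]]], path, vars[j], allow_empty = TRUE)
  lab_matrix(m)
}

#' @rdname read_wide_matrix
#' @param x A [lab_matrix()] or matrix.
#' @export
write_wide_matrix <- function(x, path) {
  v <- lab_values(x)
  header <- paste(c("patient_id", colnames(v)), collapse = ",")
  body <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], fmt_num(v[i, ])), collapse = ","), character(1))
  write_delim_lines(as.list(c(header, body)), path)
  invisible(path)
}

#' Read / write a 0/1 missingness mask
#'
#' Same layout as the wide matrix; cells are 0 (kept) or 1 (removed).
#'
#' @param path File path.
#' @return `read_mask()`: a logical matrix; the writer returns the path.
#' @export
read_mask <- function(path) {
  m <- lab_values(read_wide_matrix(path))
  if (!all(m %in% c(0, 1)))
    stop(basename(path), ": mask cells must be 0 or 1", call. = FALSE)
  m == 1
}

#' @rdname read_mask
#' @param mask Logical matrix.
#' @export
write_mask <- function(mask, path) {
  write_wide_matrix(mask * 1, path)
}
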