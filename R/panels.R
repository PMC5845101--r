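#' Default LOINC panel map for the 28 most frequently ordered laboratory tests
#'
#' The 28 assays most commonly present in adult outpatient EHR data, grouped
#' into the panels on which they are jointly ordered: the complete blood count
#' (CBC, including the automated differential neutrophil count), the routine
#' serum chemistry panel, and the lipid panel. Panel membership matters in two
#' places: the synthetic generator decides observation at the panel level
#' (labs on one requisition are ordered together), and presence prediction
#' excludes a target's panel co-members from its feature set (their presence
#' is trivially informative).
#'
#' @return A data.frame with columns `loinc` (code string), `panel`
#'   (`"cbc"`, `"chemistry"` or `"lipids"`) and `description`.
#' @export
#' @examples
#' table(default_panel_map()$panel)
default_panel_map <- function() {
  data.frame(
    loinc = c(
      "718-7", "4544-3", "787-2", "786-4", "785-6", "6690-2", "789-8",
      "788-0", "32623-1", "777-3", "751-8",
      "2345-7", "2160-0", "2823-3", "3094-0", "2951-2", "2075-0", "2028-9",
      "17861-6", "1743-4", "30239-8", "1975-2", "2885-2", "10466-1",
      "2093-3", "2571-8", "2085-9", "13457-7"
    ),
    panel = c(rep("cbc", 11), rep("chemistry", 13), rep("lipids", 4)),
    description = c(
      "Hemoglobin", "Hematocrit", "MCV", "MCHC", "MCH", "Leukocytes",
      "Erythrocytes", "RDW", "Mean platelet volume", "Platelets",
      "Neutrophils",
      "Glucose", "Creatinine", "Potassium", "Urea nitrogen", "Sodium",
      "Chloride", "Carbon dioxide", "Calcium", "ALT", "AST",
      "Total bilirubin", "Total protein", "Anion gap",
      "Total cholesterol", "Triglycerides", "HDL cholesterol",
      "LDL cholesterol"
    ),
    stringsAsFactors = FALSE
  )
}

# Validate / normalize a user-supplied panel map against a variable set.
check_panel_map <- function(panel_map, variables) {
  if (!is.data.frame(panel_map) || !all(c("loinc", "panel") %in% names(panel_map)))
    stop("`panel_map` must be a data.frame with columns 'loinc' and 'panel'",
         call. = FALSE)
  if (anyDuplicated(panel_map$loinc))
    stop("`panel_map` contains duplicated loinc codes", call. = FALSE)
  missing_vars <- setdiff(variables, panel_map$loinc)
  if (length(missing_vars))
    stop("variables absent from `panel_map`: ",
         paste(utils::head(missing_vars, 5), collapse = ", "), call. = FALSE)
  panel_map
}
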