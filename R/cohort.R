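#' @name cohort
#' @title Hospitalization cohort tables
#'
#' @description
#' A `cohort_table` is a plain data frame, one row per hospitalization, with
#' a documented column dictionary: hospital id, tier, demographics, 29
#' binary comorbidity indicators (`cm_*`), broad and fine principal
#' diagnosis categories, admission-route indicators, 11 admission labs
#' (`lab_*`), the 30-day mortality outcome `died_30d`, and
#' `predicted_mortality` (filled by [fit_risk_model()]).
NULL

#' Column dictionary for cohort tables
#'
#' @return Data frame with `column`, `type` (`id`, `integer`, `continuous`,
#'   `categorical`, `binary`, `probability`) and `role`.
#' @export
cohort_dictionary <- function() {
  d <- rbind(
    data.frame(column = "hospital_id", type = "id", role = "key"),
    data.frame(column = "tier", type = "integer", role = "stratum"),
    data.frame(column = "age", type = "continuous", role = "covariate"),
    data.frame(column = "sex", type = "categorical", role = "covariate"),
    data.frame(column = "race_ethnicity", type = "categorical",
               role = "covariate"),
    data.frame(column = "dx_category", type = "categorical",
               role = "covariate"),
    data.frame(column = "fine_dx_category", type = "categorical",
               role = "eligibility"),
    data.frame(column = paste0("cm_", comorbidity_names()), type = "binary",
               role = "covariate"),
    data.frame(column = c("surgical", "ed_admission", "nursing_facility"),
               type = "binary", role = "covariate"),
    data.frame(column = c("transfer_from_va", "organ_transplant"),
               type = "binary", role = "eligibility"),
    data.frame(column = paste0("lab_", lab_names()), type = "continuous",
               role = "covariate"),
    data.frame(column = "died_30d", type = "binary", role = "outcome"),
    data.frame(column = "predicted_mortality", type = "probability",
               role = "severity"))
  rownames(d) <- NULL
  d
}

mandatory_columns <- function() {
  setdiff(cohort_dictionary()$column, "predicted_mortality")
}

#' Validate a data frame as a cohort table
#'
#' Checks the column dictionary: all mandatory columns present, indicator
#' columns strictly 0/1, labs finite. Unknown columns are preserved as
#' passthrough.
#'
#' @param df Data frame.
#' @return The validated data frame with class `cohort_table`.
#' @export
as_cohort_table <- function(df) {
  if (!is.data.frame(df)) stop("cohort must be a data frame")
  if (nrow(df) == 0) stop("cohort has 0 rows")
  miss <- setdiff(mandatory_columns(), names(df))
  if (length(miss) > 0)
    stop("cohort is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  dict <- cohort_dictionary()
  for (cl in dict$column[dict$type == "binary"]) {
    bad <- which(!(df[[cl]] %in% c(0L, 1L)))
    if (length(bad) > 0)
      stop(sprintf("non-binary value in indicator column '%s' at row %d",
                   cl, bad[1]))
  }
  for (cl in dict$column[dict$type == "continuous"]) {
    if (any(!is.finite(df[[cl]])))
      stop(sprintf("non-finite value in continuous column '%s'", cl))
  }
  if (!"predicted_mortality" %in% names(df))
    df$predicted_mortality <- NA_real_
  df$predicted_mortality <- as.numeric(df$predicted_mortality)
  pm <- df$predicted_mortality
  if (any(!is.na(pm) & (pm <= 0 | pm >= 1)))
    stop("predicted_mortality must lie strictly in (0, 1)")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read a cohort table from CSV
#'
#' @param path CSV file with the [cohort_dictionary()] columns.
#' @return A validated `cohort_table`.
#' @export
load_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_cohort_table(df)
}

#' Write a cohort table to CSV
#'
#' @param cohort A `cohort_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Write hospital truth profiles as a JSON sidecar
#'
#' @param profiles List of `hospital_profile` objects from
#'   [generate_system()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  jsonlite::write_json(lapply(profiles, unclass), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d hospitalizations at %d hospitals; %s\n",
              nrow(x), length(unique(x$hospital_id)),
              if (all(is.na(x$predicted_mortality)))
                "predicted mortality not yet fitted"
              else "predicted mortality fitted"))
  invisible(x)
}
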