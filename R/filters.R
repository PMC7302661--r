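#' @name cohort_filters
#' @title Eligibility cascade
#'
#' @description
#' Applies the cohort exclusions in a fixed, audited order: (1)
#' transfers from another system hospital, (2) organ-transplant
#' hospitalizations, (3) missing principal diagnosis, (4) rare principal
#' diagnoses (fine category occurring in fewer than 1 in 300
#' hospitalizations of the remaining cohort), (5) hospitals left with fewer
#' rows than `template_size * ratio` (the matching-ratio guarantee), (6)
#' hospitals whose share of psychiatric / substance-abuse admissions
#' exceeds a threshold. Every step is logged with rows and hospitals
#' excluded, CONSORT style.
NULL

#' Minimum eligible volume for a hospital
#'
#' A hospital must retain at least `template_size * ratio` eligible rows to
#' guarantee the matching ratio (e.g. 300 x 3 = 900; per-stratum, a
#' 50-surgical / 250-non-surgical template needs pools of 150 and 750).
#'
#' @param template_size Template size (or stratum size).
#' @param ratio Required pool-to-template ratio (default 3).
#' @return Integer minimum volume.
#' @export
min_volume <- function(template_size, ratio = 3L) {
  if (template_size <= 0 || ratio <= 0)
    stop("template_size and ratio must be positive")
  as.integer(template_size) * as.integer(ratio)
}

#' Rare fine principal-diagnosis categories
#'
#' A fine category is rare when its count is strictly below `nrow / 300`
#' (i.e. it occurred in fewer than 1 in 300 hospitalizations of the cohort
#' passed in).
#'
#' @param cohort A `cohort_table` (conventionally, after the transfer /
#'   transplant / missing-diagnosis exclusions).
#' @param per Rarity denominator (default 300).
#' @return Character vector of rare `fine_dx_category` values.
#' @export
rare_categories <- function(cohort, per = 300) {
  if (nrow(cohort) == 0) stop("empty cohort")
  if (!"fine_dx_category" %in% names(cohort))
    stop("fine_dx_category column is required")
  tab <- table(cohort$fine_dx_category)
  cutoff <- nrow(cohort) / per
  names(tab)[tab < cutoff]
}

#' Apply the eligibility cascade
#'
#' @param cohort A `cohort_table`.
#' @param template_size Template size used for the volume rule.
#' @param ratio Matching-ratio requirement (default 3).
#' @param psych_threshold Hospitals with a strictly greater share of
#'   psychiatric / substance-abuse admissions are excluded (default 0.90).
#' @param rare_per Rarity denominator for the rare-diagnosis rule
#'   (default 300).
#' @param rare_denominator `"post_row_exclusions"` (default) computes rare
#'   categories on the cohort remaining after steps 1-3; `"input"` uses the
#'   full input cohort.
#' @return List with `cohort` (eligible rows) and `log` (an
#'   `exclusion_log` data frame: rule, rows excluded, hospitals excluded,
#'   rows and hospitals remaining after each step).
#' @export
apply_exclusions <- function(cohort, template_size = 300, ratio = 3L,
                             psych_threshold = 0.90, rare_per = 300,
                             rare_denominator = c("post_row_exclusions",
                                                  "input")) {
  stopifnot(inherits(cohort, "cohort_table"))
  rare_denominator <- match.arg(rare_denominator)
  steps <- list()
  note <- function(rule, before, after) {
    hb <- unique(before$hospital_id); ha <- unique(after$hospital_id)
    steps[[length(steps) + 1]] <<- data.frame(
      rule = rule,
      rows_excluded = nrow(before) - nrow(after),
      hospitals_excluded = length(setdiff(hb, ha)),
      rows_remaining = nrow(after),
      hospitals_remaining = length(ha))
    after
  }
  cur <- cohort

  cur <- note("transfer_from_va", cur, cur[cur$transfer_from_va == 0, ])
  cur <- note("organ_transplant", cur, cur[cur$organ_transplant == 0, ])
  cur <- note("missing_principal_dx", cur, cur[!is.na(cur$dx_category), ])

  denom <- if (rare_denominator == "input") cohort else cur
  rare <- rare_categories(denom, per = rare_per)
  cur <- note("rare_principal_dx", cur,
              cur[!(cur$fine_dx_category %in% rare), ])

  minv <- min_volume(template_size, ratio)
  vol <- table(cur$hospital_id)
  keep_h <- names(vol)[vol >= minv]
  cur <- note("volume_below_matching_ratio", cur,
              cur[cur$hospital_id %in% keep_h, ])

  psy <- tapply(cur$dx_category == "psych_substance", cur$hospital_id, mean)
  keep_h <- names(psy)[psy <= psych_threshold]
  cur <- note("psych_substance_share", cur,
              cur[cur$hospital_id %in% keep_h, ])

  log <- do.call(rbind, steps)
  log <- cbind(step = seq_len(nrow(log)), log)
  class(log) <- c("exclusion_log", "data.frame")
  attr(log, "rows_in") <- nrow(cohort)
  attr(log, "hospitals_in") <- length(unique(cohort$hospital_id))
  attr(log, "rare_categories") <- rare
  if (nrow(cur) == 0) {
    warning("all hospitals excluded by the eligibility cascade")
    return(list(cohort = cur, log = log))
  }
  list(cohort = as_cohort_table(as.data.frame(cur)), log = log)
}

#' Write an exclusion log as a CONSORT-style JSON report
#'
#' @param log An `exclusion_log`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(log, path) {
  jsonlite::write_json(
    list(rows_in = attr(log, "rows_in"),
         hospitals_in = attr(log, "hospitals_in"),
         rare_categories = attr(log, "rare_categories"),
         steps = as.data.frame(log)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat(sprintf("<exclusion_log> %d rows at %d hospitals in\n",
              attr(x, "rows_in"), attr(x, "hospitals_in")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %d. %-28s -%7d rows, -%2d hospitals (%d rows remain)\n",
                x$step[i], x$rule[i], x$rows_excluded[i],
                x$hospitals_excluded[i], x$rows_remaining[i]))
  invisible(x)
}
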