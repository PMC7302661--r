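#' @name template_selection
#' @title Template selection
#'
#' @description
#' The template is a fixed set of m hospitalizations (default 300) used as
#' the common yardstick for every hospital. Candidate templates are simple
#' random samples without replacement from the eligible cohort; the
#' selected template is the candidate whose mean vector over a selection
#' roster has the smallest Mahalanobis distance to the cohort-wide mean,
#' with the covariance estimated from the full eligible cohort. In the
#' tiered variant one template is selected per critical-care tier, with the
#' surgical proportion optionally fixed to that of the tier's median
#' hospital.
NULL

#' Default template-selection roster
#'
#' Predicted mortality, observed mortality, sex, race/ethnicity, surgical
#' indicator, the 7 broad diagnosis categories, and seven major
#' comorbidities (congestive heart failure, chronic pulmonary disease,
#' paralysis, renal failure, liver disease, metastatic cancer, depression).
#'
#' @return Character vector of roster entries.
#' @export
default_selection_roster <- function() {
  c("predicted_mortality", "died_30d", "sex", "race_ethnicity", "surgical",
    "dx_category",
    paste0("cm_", c("chf", "chronic_pulm", "paralysis", "renal_failure",
                    "liver_disease", "mets_cancer", "depression")))
}

# numeric design over a roster: categorical variables enter as one-hot
# indicators with one reference level dropped (keeps the covariance better
# conditioned); everything else must already be numeric
roster_design <- function(cohort, roster) {
  cols <- list()
  for (v in roster) {
    if (v == "sex") {
      cols[["sexM"]] <- as.numeric(cohort$sex == "M")
    } else if (v == "race_ethnicity") {
      for (r in setdiff(race_levels(), "white"))
        cols[[paste0("race_", r)]] <- as.numeric(cohort$race_ethnicity == r)
    } else if (v == "dx_category") {
      for (d in setdiff(dx_categories(), "other"))
        cols[[paste0("dx_", d)]] <- as.numeric(cohort$dx_category == d)
    } else if (v %in% names(cohort)) {
      x <- cohort[[v]]
      if (!is.numeric(x))
        stop("roster variable is not numeric and has no encoding rule: ", v)
      cols[[v]] <- x
    } else {
      stop("roster variable not found in cohort: ", v)
    }
  }
  X <- do.call(cbind, cols)
  if (any(!is.finite(X))) stop("non-finite value in roster design")
  X
}

#' Mahalanobis distance between two mean vectors
#'
#' `sqrt((u - v)' cov^- (u - v))` with a Moore-Penrose pseudo-inverse, so
#' singular covariances (e.g. from collinear indicators) are handled by
#' measuring distance within the supported subspace.
#'
#' @param u,v Numeric vectors of equal length.
#' @param cov Symmetric positive-semidefinite covariance matrix.
#' @return Nonnegative scalar distance.
#' @export
mahalanobis_distance <- function(u, v, cov) {
  if (length(u) != length(v)) stop("u and v differ in length")
  cov <- as.matrix(cov)
  if (nrow(cov) != length(u) || ncol(cov) != length(u))
    stop("cov dimensions do not match the vectors")
  if (!isSymmetric(cov, tol = 1e-8)) stop("cov must be symmetric")
  d <- u - v
  sqrt(max(0, drop(t(d) %*% MASS::ginv(cov) %*% d)))
}

#' Draw candidate templates
#'
#' `k` independent simple random samples of `m` rows without replacement.
#'
#' @param cohort A `cohort_table` (or any data frame).
#' @param m Template size.
#' @param k Number of candidates.
#' @param seed Integer seed.
#' @param stratify_surgical Optional `c(n_surgical, n_nonsurgical)` split;
#'   when given, each candidate is drawn stratified on the surgical
#'   indicator with exactly that composition.
#' @return List of `k` integer row-index vectors.
#' @export
draw_candidates <- function(cohort, m = 300, k = 1000, seed,
                            stratify_surgical = NULL) {
  if (missing(seed)) stop("seed must be given")
  n <- nrow(cohort)
  if (m > n) stop("template size m exceeds cohort size")
  if (k < 1) stop("k must be >= 1")
  set.seed(seed)
  if (is.null(stratify_surgical)) {
    lapply(seq_len(k), function(i) sort(sample.int(n, m)))
  } else {
    ns <- stratify_surgical[1]; nn <- stratify_surgical[2]
    stopifnot(ns + nn == m)
    si <- which(cohort$surgical == 1); ni <- which(cohort$surgical == 0)
    if (length(si) < ns || length(ni) < nn)
      stop("cohort too small for the requested surgical stratification")
    lapply(seq_len(k), function(i)
      sort(c(sample(si, ns), sample(ni, nn))))
  }
}

#' Select the most representative template
#'
#' Scores every candidate by the Mahalanobis distance between the candidate
#' mean and the cohort mean over the selection roster (covariance from the
#' full cohort, pseudo-inverse for singular cases; zero-variance roster
#' columns are dropped with a warning). Ties break by candidate index.
#'
#' @param cohort Eligible `cohort_table` the candidates index into.
#' @param candidates List of row-index vectors from [draw_candidates()].
#' @param roster Selection roster, see [default_selection_roster()].
#' @param tier Optional tier label carried into the template.
#' @return A `template` object: `indices`, `data` (the template rows),
#'   `roster`, `distance`, `candidate_distances`, `tier`, `surgical_count`.
#' @export
select_template <- function(cohort, candidates,
                            roster = default_selection_roster(),
                            tier = NA) {
  if (length(candidates) < 1) stop("at least one candidate is required")
  X <- roster_design(cohort, roster)
  keep <- apply(X, 2, function(cl) sd(cl) > 0)
  if (!all(keep)) {
    warning("dropping zero-variance roster column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  pop_mean <- colMeans(X)
  cinv <- MASS::ginv(cov(X))
  dist <- vapply(candidates, function(idx) {
    d <- colMeans(X[idx, , drop = FALSE]) - pop_mean
    sqrt(max(0, drop(t(d) %*% cinv %*% d)))
  }, numeric(1))
  best <- which.min(dist) # which.min takes the first index on ties
  idx <- candidates[[best]]
  structure(list(indices = idx,
                 data = cohort[idx, , drop = FALSE],
                 roster = roster,
                 distance = dist[best],
                 candidate_index = best,
                 candidate_distances = dist,
                 tier = tier,
                 surgical_count = sum(cohort$surgical[idx])),
            class = "template")
}

#' Fix the template's surgical mix to the tier's median hospital
#'
#' Computes the median across hospitals of the within-hospital surgical
#' proportion, rounds `m * p` to the surgical stratum size, and flags
#' hospitals whose surgical or non-surgical pools cannot support the
#' required matching ratio in either stratum.
#'
#' @param tier_cohort `cohort_table` of the hospitals in one tier.
#' @param m Template size.
#' @param ratio Matching-ratio requirement (default 3).
#' @return List: `n_surgical`, `n_nonsurgical`, `p_star`, and `eligibility`
#'   (per-hospital pools and an `eligible` flag).
#' @export
fix_surgical_mix <- function(tier_cohort, m = 300, ratio = 3L) {
  if (nrow(tier_cohort) == 0) stop("empty tier cohort")
  p_by_h <- tapply(tier_cohort$surgical, tier_cohort$hospital_id, mean)
  p_star <- median(p_by_h)
  n_s <- as.integer(round(m * p_star))
  n_n <- as.integer(m) - n_s
  if (p_star > 0 && p_star < 1 && (n_s == 0L || n_s == m))
    warning("surgical stratum rounds to an empty stratum at m = ", m)
  pool_s <- tapply(tier_cohort$surgical == 1, tier_cohort$hospital_id, sum)
  pool_n <- tapply(tier_cohort$surgical == 0, tier_cohort$hospital_id, sum)
  elig <- data.frame(hospital_id = names(p_by_h),
                     surgical_pool = as.integer(pool_s),
                     nonsurgical_pool = as.integer(pool_n),
                     eligible = pool_s >= min_volume(max(n_s, 1L), ratio) *
                       (n_s > 0) & pool_n >= min_volume(max(n_n, 1L), ratio) *
                       (n_n > 0),
                     row.names = NULL)
  list(n_surgical = n_s, n_nonsurgical = n_n, p_star = unname(p_star),
       eligibility = elig)
}

#' Select one template per critical-care tier
#'
#' @param cohort Eligible `cohort_table` with a `tier` column.
#' @param m Template size per tier.
#' @param k Candidates per tier.
#' @param seed Integer seed.
#' @param roster Selection roster.
#' @param fix_surgical Fix each tier template's surgical mix to the tier's
#'   median hospital (default TRUE).
#' @param ratio Matching-ratio requirement used for stratum eligibility.
#' @return Named list of `template` objects, one per tier present.
#' @export
select_tier_templates <- function(cohort, m = 300, k = 1000, seed,
                                  roster = default_selection_roster(),
                                  fix_surgical = TRUE, ratio = 3L) {
  if (missing(seed)) stop("seed must be given")
  tiers <- sort(unique(cohort$tier))
  out <- list()
  for (tr in tiers) {
    sub <- cohort[cohort$tier == tr, , drop = FALSE]
    strat <- NULL
    mix <- NULL
    if (fix_surgical) {
      mix <- fix_surgical_mix(sub, m, ratio)
      strat <- c(mix$n_surgical, mix$n_nonsurgical)
      if (strat[1] == 0) strat <- NULL # degenerate stratum: plain draws
    }
    cand <- draw_candidates(sub, m, k, seed = sub_seed(seed, tr),
                            stratify_surgical = strat)
    tmpl <- select_template(sub, cand, roster, tier = tr)
    tmpl$surgical_mix <- mix
    out[[paste0("tier", tr)]] <- tmpl
  }
  out
}

#' Persist a template as CSV rows plus JSON metadata
#'
#' @param template A `template`.
#' @param csv_path,json_path Output paths.
#' @return `csv_path`, invisibly.
#' @export
write_template <- function(template, csv_path, json_path) {
  write.csv(as.data.frame(template$data), csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(roster = template$roster, distance = template$distance,
         candidate_index = template$candidate_index,
         tier = template$tier, size = length(template$indices),
         surgical_count = template$surgical_count),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv_path)
}

#' @export
print.template <- function(x, ...) {
  cat(sprintf(
    "<template> %d cases%s; selection distance %.4f (candidate %d of %d)\n",
    length(x$indices),
    if (!is.na(x$tier)) sprintf(" (tier %s)", x$tier) else "",
    x$distance, x$candidate_index, length(x$candidate_distances)))
  invisible(x)
}
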