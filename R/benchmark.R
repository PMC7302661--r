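#' @name benchmarking
#' @title Hospital ranking on matched samples, with a regression comparator
#'
#' @description
#' Template-matching benchmark: the matched samples of all hospitals are
#' stacked and 30-day mortality is modelled by hierarchical logistic
#' regression with a fixed effect per hospital (sum-to-zero centred, so an
#' effect is a deviation from the average hospital), adjustment for the
#' logit of predicted mortality, and a random intercept per template case
#' (each template case indexes a cluster of one matched row per hospital).
#' Hospitals are ranked by the estimated fixed effect, lowest (best) first.
#' The conventional comparator is a random-intercept-per-hospital logistic
#' model on the entire eligible cohort adjusted for predicted risk, ranked
#' by the empirical-Bayes hospital intercepts. Hospitals are then
#' categorized into top quintile / middle three quintiles / bottom
#' quintile, and category assignments of two benchmarks are compared by
#' chi-square.
NULL

logit_pred <- function(p) qlogis(pmin(pmax(p, 1e-10), 1 - 1e-10))

new_benchmark_report <- function(df, method, metadata = list()) {
  df <- df[order(df$estimate, df$hospital_id), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(df, class = c("benchmark_report", "data.frame"),
            method = method, metadata = metadata)
}

#' Rank hospitals on 30-day mortality of their matched samples
#'
#' Hospitals whose match was ineligible, non-converged or incomplete are
#' omitted (and listed in the metadata). A hospital with no deaths (or no
#' survivors) among its matched rows would separate the likelihood; such
#' hospitals receive two half-weight pseudo-observations (one death, one
#' survival, in their own pseudo-clusters) - a weak ridge towards the
#' average - and are flagged. If the template-case random-intercept
#' variance is estimated as zero (or the mixed fit fails), the model falls
#' back to conditional logistic regression stratified on template case,
#' flagged in the metadata.
#'
#' @param match_results List of `match_result` from [match_hospitals()].
#' @param include_infeasible Keep hospitals whose fine balance was not
#'   attained (default TRUE, mirroring an audit-but-do-not-drop policy).
#' @param estimator `"auto"` (mixed model, falling back to conditional
#'   logistic when the template-case variance degenerates or the fit
#'   fails) or `"conditional"` (go straight to conditional logistic
#'   regression on template-case strata, the classical estimator for 1:1
#'   matched data and much faster for small studies).
#' @return A `benchmark_report`: hospital_id, estimate (log-odds deviation
#'   from the average hospital), se, rank (1 = lowest mortality),
#'   method `"template_matching"`.
#' @export
rank_matched <- function(match_results, include_infeasible = TRUE,
                         estimator = c("auto", "conditional")) {
  estimator <- match.arg(estimator)
  usable <- Filter(function(r) {
    !is.null(r$pairs) && r$eligible && !r$non_converged &&
      (include_infeasible || r$feasible)
  }, match_results)
  if (length(usable) < 2)
    stop("need matched samples from at least 2 hospitals")
  stacked <- do.call(rbind, lapply(usable, function(r) {
    d <- as.data.frame(r$matched_data)
    data.frame(hospital = r$hospital_id,
               slot = r$pairs$template_index,
               died = d$died_30d,
               lp = logit_pred(d$predicted_mortality),
               w = 1)
  }))
  deaths <- tapply(stacked$died, stacked$hospital, sum)
  alive <- tapply(1 - stacked$died, stacked$hospital, sum)
  ridged <- names(deaths)[deaths == 0 | alive == 0]
  if (length(ridged) > 0) {
    aug <- do.call(rbind, lapply(ridged, function(h) {
      data.frame(hospital = h, slot = c(-1L, -2L), died = c(0L, 1L),
                 lp = mean(stacked$lp[stacked$hospital == h]), w = 0.5)
    }))
    stacked <- rbind(stacked, aug)
  }
  stacked$hospital <- factor(stacked$hospital)
  stacked$slot <- factor(stacked$slot)

  fit <- if (estimator == "conditional") NULL else tryCatch(
    suppressWarnings(lme4::glmer(
      died ~ 0 + hospital + lp + (1 | slot), data = stacked,
      family = binomial(), weights = w,
      control = lme4::glmerControl(calc.derivs = FALSE))),
    error = function(e) NULL)
  estimator <- "glmer_laplace"
  est <- se <- NULL
  if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
    cf <- lme4::fixef(fit)
    keep <- grep("^hospital", names(cf))
    est <- cf[keep]
    se <- sqrt(diag(as.matrix(vcov(fit)))[keep])
    names(est) <- names(se) <- sub("^hospital", "", names(cf)[keep])
  } else {
    # conditional likelihood given template-case strata
    estimator <- "conditional_logistic"
    cfit <- suppressWarnings(survival::clogit(
      died ~ hospital + lp + strata(slot), data = stacked,
      weights = w, method = "approximate"))
    cf <- coef(cfit)
    keep <- grep("^hospital", names(cf))
    lev <- levels(stacked$hospital)
    est <- c(0, cf[keep])
    # the reference hospital's contrast has no SE of its own here
    se <- c(NA_real_, sqrt(diag(as.matrix(vcov(cfit)))[keep]))
    names(est) <- names(se) <- lev
  }
  est <- est - mean(est) # sum-to-zero: deviation from the average hospital
  df <- data.frame(hospital_id = names(est), estimate = unname(est),
                   se = unname(se))
  new_benchmark_report(df, "template_matching",
                       metadata = list(estimator = estimator,
                                       ridged_hospitals = ridged,
                                       n_hospitals = nrow(df),
                                       omitted = setdiff(
                                         names(match_results),
                                         names(usable))))
}

#' Rank hospitals by regression on the entire cohort
#'
#' Random-intercept-per-hospital logistic model adjusted for the logit of
#' predicted mortality; hospitals ranked by their empirical-Bayes
#' (posterior-mode) intercepts.
#'
#' @param cohort Eligible `cohort_table` with `predicted_mortality` filled.
#' @return A `benchmark_report` with method `"regression"`.
#' @export
rank_regression <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (length(unique(cohort$hospital_id)) < 2)
    stop("regression benchmarking needs >= 2 hospitals")
  if (all(is.na(cohort$predicted_mortality)))
    stop("predicted_mortality has not been fitted")
  d <- data.frame(hospital = factor(cohort$hospital_id),
                  died = cohort$died_30d,
                  lp = logit_pred(cohort$predicted_mortality))
  fit <- suppressWarnings(lme4::glmer(
    died ~ lp + (1 | hospital), data = d, family = binomial(),
    control = lme4::glmerControl(calc.derivs = FALSE)))
  re <- lme4::ranef(fit, condVar = TRUE)$hospital
  pv <- attr(re, "postVar")
  df <- data.frame(hospital_id = rownames(re),
                   estimate = re[, 1],
                   se = sqrt(pv[1, 1, ]))
  new_benchmark_report(df, "regression",
                       metadata = list(
                         estimator = "glmer_laplace",
                         singular = lme4::isSingular(fit, tol = 1e-5),
                         re_sd = sqrt(unlist(lme4::VarCorr(fit))[[1]]),
                         n_hospitals = nrow(df)))
}

#' Assign quintile performance categories
#'
#' Top quintile (best, lowest-mortality ranks) and bottom quintile each
#' hold `ceiling(H / 5)` hospitals; the remainder are `median`.
#'
#' @param report A `benchmark_report` with ranks.
#' @return The report with a `category` column
#'   (`top` / `median` / `bottom`).
#' @export
categorize <- function(report) {
  H <- nrow(report)
  if (H < 5) stop("need at least 5 hospitals to form quintiles")
  nq <- ceiling(H / 5)
  report$category <- ifelse(report$rank <= nq, "top",
                            ifelse(report$rank > H - nq, "bottom",
                                   "median"))
  report$category <- factor(report$category,
                            levels = c("top", "median", "bottom"))
  report
}

#' Compare performance-category assignments of two benchmarks
#'
#' Cross-tabulates the categories of the common hospitals and tests the
#' 3 x 3 table with Pearson chi-square.
#'
#' @param report_a,report_b Categorized `benchmark_report`s over the same
#'   hospital set.
#' @return List: `table` (3 x 3), `statistic`, `df`, `p_value`,
#'   `agreement` (share of hospitals assigned the same category).
#' @export
compare_rankings <- function(report_a, report_b) {
  if (is.null(report_a$category) || is.null(report_b$category))
    stop("categorize() both reports first")
  common <- intersect(report_a$hospital_id, report_b$hospital_id)
  if (length(common) == 0) stop("reports share no hospitals")
  if (!setequal(report_a$hospital_id, report_b$hospital_id))
    warning("reports cover different hospital sets; comparing the ",
            length(common), " common hospitals")
  ca <- report_a$category[match(common, report_a$hospital_id)]
  cb <- report_b$category[match(common, report_b$hospital_id)]
  tab <- table(a = ca, b = cb)
  ct <- chi_square_independence(tab)
  list(table = tab, statistic = ct$statistic, df = ct$df,
       p_value = ct$p_value, agreement = mean(ca == cb))
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> method %s: %d hospitals ranked\n",
              attr(x, "method"), nrow(x)))
  print(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
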