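#' @name validation
#' @title Simulation studies of benchmark validity
#'
#' @description
#' End-to-end simulation replicates on synthetic hospital systems with
#' known quality effects: generate, fit the risk model, apply the
#' eligibility cascade, select a template, match every eligible hospital,
#' audit balance, and rank hospitals by template matching and by the
#' regression comparator. Used to measure how well each benchmark recovers
#' the true hospital effects (Spearman correlation of true effect with
#' estimated rank) and how case-mix heterogeneity degrades balance and
#' cross-method agreement.
NULL

#' One benchmark-recovery replicate on a synthetic system
#'
#' @param seed Integer seed for this replicate.
#' @param n_hospitals,volume_range,heterogeneity,quality_sd Generator
#'   settings, see [system_config()].
#' @param template_size,candidates,ratio Template settings.
#' @param spec A [match_spec()] for the matching run; default: the
#'   high-prognostic-significance roster with a near-exact sex constraint
#'   and no fine balance, thinned to 8 neighbours per template case.
#' @param second_spec Optional second [match_spec()]; when given, the
#'   replicate also reports the category agreement between the two
#'   matching runs.
#' @param estimator Passed to [rank_matched()].
#' @param balance_threshold Balance p-value cut.
#' @param risk_roster Risk-model roster (default: the full roster without
#'   the fine-diagnosis indicators, which matches the generating model).
#' @return List: `spearman_matched`, `spearman_regression` (true quality
#'   effect vs estimated rank over each method's ranked hospitals),
#'   `n_ranked`, `n_unbalanced` (variables failing the omnibus balance
#'   test after matching), `agreement_vs_regression`, and, with a second
#'   spec, `agreement_between_runs` (category agreement shares).
#' @export
benchmark_recovery_replicate <- function(
    seed, n_hospitals = 40, volume_range = c(300, 3000),
    heterogeneity = 1, quality_sd = 0.3,
    template_size = 300, candidates = 50, ratio = 3L,
    spec = match_spec(near_exact = "sex", fine_balance = NULL,
                      sparse_neighbors = 8),
    second_spec = NULL,
    estimator = "auto",
    balance_threshold = 0.05,
    risk_roster = setdiff(default_risk_roster(), "fine_top20")) {
  cfg <- system_config(n_hospitals = n_hospitals,
                       volume_range = volume_range,
                       heterogeneity = heterogeneity,
                       quality_sd = quality_sd)
  gen <- generate_system(cfg, seed = seed)
  fit <- suppressWarnings(fit_risk_model(gen$cohort, risk_roster))
  ex <- apply_exclusions(fit$cohort, template_size, ratio)
  eligible <- ex$cohort
  cand <- draw_candidates(eligible, template_size, candidates,
                          seed = sub_seed(seed, 1))
  tmpl <- suppressWarnings(select_template(eligible, cand))

  run_one <- function(sp) {
    mr <- match_hospitals(tmpl, eligible, sp)
    rep <- rank_matched(mr, estimator = estimator)
    if (nrow(rep) >= 5) rep <- categorize(rep)
    # constant rare indicators in small matched samples are expected
    # here; the degenerate-balanced warning is for interactive use
    bal <- suppressWarnings(balance_table(
      lapply(Filter(function(r) !is.null(r$matched_data), mr),
             `[[`, "matched_data"),
      roster = sp$distance_roster, threshold = balance_threshold))
    list(report = rep, n_unbalanced = attr(bal, "n_unbalanced"))
  }
  r1 <- run_one(spec)
  reg <- rank_regression(eligible)
  if (nrow(reg) >= 5) reg <- categorize(reg)

  truth <- gen$truth
  sp_rank <- function(rep) {
    q <- truth$quality_effect[match(rep$hospital_id, truth$hospital_id)]
    cor(q, rep$rank, method = "spearman")
  }
  out <- list(
    spearman_matched = sp_rank(r1$report),
    spearman_regression = sp_rank(reg),
    n_ranked = nrow(r1$report),
    n_unbalanced = r1$n_unbalanced,
    agreement_vs_regression =
      if (!is.null(r1$report$category) && !is.null(reg$category))
        compare_rankings(r1$report, reg)$agreement else NA_real_)
  if (!is.null(second_spec)) {
    r2 <- run_one(second_spec)
    out$n_unbalanced_second <- r2$n_unbalanced
    out$agreement_between_runs <-
      if (!is.null(r1$report$category) && !is.null(r2$report$category))
        compare_rankings(r1$report, r2$report)$agreement else NA_real_
  }
  out
}

#' One two-hospital separation replicate
#'
#' Two hospitals with true quality effects 0 and +1 (log-odds), identical
#' case-mix distribution; both are matched to a common template and ranked
#' on their matched samples. Returns whether the benchmark ordered them
#' correctly (worse-quality hospital ranked worse).
#'
#' @param seed Integer seed.
#' @param template_size Template size (pools are sized at the matching
#'   ratio so both hospitals stay eligible).
#' @param effect True quality effect of the worse hospital.
#' @return Logical: TRUE when the hospital with the positive mortality
#'   effect is ranked last.
#' @export
separation_replicate <- function(seed, template_size = 300, effect = 1) {
  cfg <- system_config(n_hospitals = 2,
                       volume_range = c(3 * template_size,
                                        3 * template_size + 100),
                       heterogeneity = 0, quality_sd = 0,
                       transfer_rate = 0, transplant_rate = 0,
                       missing_dx_rate = 0)
  gen <- generate_system(cfg, seed = seed)
  # overwrite the (zero) quality effects with the contrast under study
  # and redraw the outcomes from the true model
  set.seed(sub_seed(seed, 9))
  truth_effect <- c(0, effect)
  co <- as.data.frame(gen$cohort)
  p <- attr(gen$cohort, "true_prob")
  for (h in 1:2) {
    idx <- co$hospital_id == gen$truth$hospital_id[h]
    ph <- plogis(qlogis(p[idx]) + truth_effect[h])
    co$died_30d[idx] <- rbinom(sum(idx), 1L, ph)
  }
  cohort <- as_cohort_table(co)
  fit <- suppressWarnings(fit_risk_model(
    cohort, c("age", "sex", "dx_category", "surgical", "ed_admission",
              paste0("lab_", lab_names()))))
  cand <- draw_candidates(fit$cohort, template_size, 10,
                          seed = sub_seed(seed, 2))
  tmpl <- suppressWarnings(select_template(fit$cohort, cand))
  mr <- match_hospitals(tmpl, fit$cohort,
                        match_spec(near_exact = NULL, fine_balance = NULL,
                                   sparse_neighbors = 8))
  rep <- rank_matched(mr, estimator = "conditional")
  worst <- rep$hospital_id[which.max(rep$estimate)]
  worst == gen$truth$hospital_id[2]
}
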