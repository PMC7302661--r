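# Fixture builders. Everything is generated in code; no stored data.

# a minimal valid cohort row set with explicit overrides; defaults are a
# healthy 65-year-old cardiovascular admission
make_toy_cohort <- function(n, hospital_id = "H001", tier = 1L,
                            dx_category = "cardiovascular",
                            fine_dx_category = NULL,
                            surgical = 0L, died_30d = 0L,
                            transfer_from_va = 0L, organ_transplant = 0L,
                            age = 65, sex = "M", ed_admission = 0L,
                            predicted_mortality = NA_real_) {
  df <- data.frame(
    hospital_id = rep_len(hospital_id, n),
    tier = rep_len(tier, n),
    age = rep_len(age, n),
    sex = rep_len(sex, n),
    race_ethnicity = "white",
    dx_category = rep_len(dx_category, n),
    fine_dx_category = if (is.null(fine_dx_category))
      paste0(rep_len(dx_category, n), "_01")
    else rep_len(fine_dx_category, n),
    surgical = rep_len(as.integer(surgical), n),
    ed_admission = rep_len(as.integer(ed_admission), n),
    nursing_facility = 0L,
    transfer_from_va = rep_len(as.integer(transfer_from_va), n),
    organ_transplant = rep_len(as.integer(organ_transplant), n),
    died_30d = rep_len(as.integer(died_30d), n),
    predicted_mortality = rep_len(predicted_mortality, n),
    stringsAsFactors = FALSE)
  for (cm in paste0("cm_", comorbidity_names())) df[[cm]] <- 0L
  ctr <- templatebench::lab_names()
  centers <- c(138, 22, 65, 130, 3.6, 0.9, 9, 38, 7.39, 40, 85)
  for (i in seq_along(ctr)) df[[paste0("lab_", ctr[i])]] <- centers[i]
  as_cohort_table(df)
}

# small generated system with predicted mortality fitted and exclusions
# applied; cached per test file via local memoisation
small_eligible_system <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gen <- generate_system(
      system_config(n_hospitals = 6, volume_range = c(400, 900),
                    quality_sd = 0.3),
      seed = 2024)
    # rare fine-diagnosis indicators can near-separate at this scale;
    # the ridge fallback warning is expected and not under test here
    fit <- suppressWarnings(fit_risk_model(gen$cohort))
    ex <- apply_exclusions(fit$cohort, template_size = 80, ratio = 3)
    cache <<- list(gen = gen, fit = fit, eligible = ex$cohort,
                   log = ex$log)
    cache
  }
})

# random small matching instance on the toy scale used by the optimality
# oracles: numeric design columns only
random_match_instance <- function(m, n, n_cat = 0) {
  df_t <- data.frame(x1 = rnorm(m), x2 = rnorm(m))
  df_p <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  if (n_cat > 0) {
    df_t$grp <- sample(LETTERS[seq_len(n_cat)], m, replace = TRUE)
    df_p$grp <- sample(LETTERS[seq_len(n_cat)], n, replace = TRUE)
  }
  list(template = df_t, pool = df_p)
}
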