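#' @name synthetic
#' @title Synthetic multi-hospital cohort generation
#'
#' @description
#' Generates hospitalization-level cohorts with the statistical structure of
#' a large integrated system: many hospitals with skewed annual volumes,
#' strong between-hospital case-mix heterogeneity (demographics, comorbidity
#' prevalences, diagnosis mix, surgical and emergency-department admission
#' rates, admission laboratory values), and hospital-specific true quality
#' effects expressed as log-odds offsets on 30-day mortality. The true
#' effects give every downstream stage (matching, ranking) a
#' parameter-recovery test surface.
NULL

## ---- fixed vocabularies -------------------------------------------------

#' Names of the 29 binary comorbidity indicators
#' @return Character vector of length 29.
#' @export
comorbidity_names <- function() {
  c("chf", "arrhythmia", "valvular", "pulm_circ", "pvd", "htn",
    "paralysis", "neuro_other", "chronic_pulm", "diabetes",
    "diabetes_comp", "hypothyroid", "renal_failure", "liver_disease",
    "aids", "lymphoma", "mets_cancer", "solid_tumor", "rheumatoid",
    "coagulopathy", "obesity", "weight_loss", "fluid_electrolyte",
    "blood_loss_anemia", "deficiency_anemia", "alcohol_abuse",
    "drug_abuse", "psychoses", "depression")
}

#' Broad principal-diagnosis categories
#' @return Character vector of the 7 broad categories.
#' @export
dx_categories <- function() {
  c("cardiovascular", "psych_substance", "infection", "gastrointestinal",
    "respiratory", "genitourinary_renal", "other")
}

#' Names of the 11 admission laboratory values
#' @return Character vector of length 11.
#' @export
lab_names <- function() {
  c("sodium", "bun", "gfr", "glucose", "albumin", "bilirubin",
    "wbc", "hematocrit", "ph", "paco2", "pao2")
}

race_levels <- function() c("white", "black", "hispanic", "other")

# population prevalence of each comorbidity at the "average" hospital
elix_base_prev <- function() {
  setNames(
    c(0.18, 0.22, 0.05, 0.04, 0.12, 0.55, 0.03, 0.08, 0.25, 0.30,
      0.12, 0.10, 0.18, 0.07, 0.01, 0.02, 0.04, 0.08, 0.03, 0.05,
      0.15, 0.06, 0.20, 0.03, 0.10, 0.18, 0.12, 0.08, 0.25),
    comorbidity_names())
}

dx_base_prob <- function() {
  setNames(c(0.22, 0.18, 0.14, 0.12, 0.12, 0.08, 0.14), dx_categories())
}

lab_center <- function() {
  setNames(c(138, 22, 65, 130, 3.6, 0.9, 9, 38, 7.39, 40, 85), lab_names())
}

lab_scale <- function() {
  setNames(c(4, 12, 25, 50, 0.6, 0.8, 4, 6, 0.06, 8, 25), lab_names())
}

# fixed plausible correlation among lab z-scores (renal pair, blood gas
# pair, nutrition pair); positive definiteness asserted in tests
lab_correlation <- function() {
  nm <- lab_names()
  R <- diag(11)
  dimnames(R) <- list(nm, nm)
  R["bun", "gfr"] <- R["gfr", "bun"] <- -0.60
  R["ph", "paco2"] <- R["paco2", "ph"] <- -0.45
  R["albumin", "hematocrit"] <- R["hematocrit", "albumin"] <- 0.25
  R["sodium", "bun"] <- R["bun", "sodium"] <- 0.15
  R
}

# mean lab z-shifts by broad diagnosis category (rows = category)
dx_lab_shift <- function() {
  M <- matrix(0, 7, 11, dimnames = list(dx_categories(), lab_names()))
  M["infection", "wbc"] <- 0.8
  M["infection", "albumin"] <- -0.3
  M["respiratory", "paco2"] <- 0.5
  M["respiratory", "pao2"] <- -0.6
  M["genitourinary_renal", "bun"] <- 0.7
  M["genitourinary_renal", "gfr"] <- -0.8
  M["gastrointestinal", "hematocrit"] <- -0.3
  M["gastrointestinal", "bilirubin"] <- 0.4
  M
}

# fine principal-diagnosis categories: a refinement of the 7 broad
# categories with a long-tailed (Zipf-like) within-category frequency
# profile so that a 1-in-300 rare-diagnosis rule has something to bite on
fine_dx_table <- function() {
  n_fine <- c(cardiovascular = 12, psych_substance = 8, infection = 10,
              gastrointestinal = 10, respiratory = 8,
              genitourinary_renal = 8, other = 16)
  out <- lapply(names(n_fine), function(cat) {
    k <- n_fine[[cat]]
    w <- (1 / seq_len(k))^1.3
    data.frame(dx_category = cat,
               fine_dx_category = sprintf("%s_%02d", cat, seq_len(k)),
               prob = w / sum(w), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## ---- outcome model ------------------------------------------------------

#' Default true 30-day mortality model coefficients
#'
#' The generating outcome model is a logistic regression on age, sex,
#' race/ethnicity, the 29 comorbidities, broad diagnosis category, surgical
#' indicator, ED-admission indicator, nursing-facility indicator and the 11
#' admission labs (as z-scores), plus the hospital's quality effect. The
#' coefficient values are package defaults chosen to yield a plausible
#' acute-care mortality gradient and a pooled 30-day mortality near 5%;
#' no published coefficient set exists for this purpose.
#'
#' @return Named list of coefficient blocks.
#' @export
default_outcome_coefficients <- function() {
  cm <- setNames(numeric(29), comorbidity_names())
  cm[c("chf", "arrhythmia", "renal_failure", "liver_disease",
       "mets_cancer", "solid_tumor", "coagulopathy", "weight_loss",
       "fluid_electrolyte", "chronic_pulm", "paralysis", "lymphoma",
       "pvd", "neuro_other")] <-
    c(0.45, 0.20, 0.30, 0.40, 0.95, 0.30, 0.40, 0.50,
      0.45, 0.25, 0.30, 0.40, 0.15, 0.25)
  cm[c("obesity", "depression", "htn")] <- c(-0.15, -0.10, -0.05)
  dx <- setNames(c(0.20, -1.30, 0.55, 0.10, 0.35, 0.20, 0.00),
                 dx_categories())
  labs <- setNames(c(-0.05, 0.30, -0.20, 0.05, -0.35, 0.15,
                     0.15, -0.10, -0.20, 0.05, -0.10), lab_names())
  list(intercept = -3.60,
       age_per_10y = 0.38,
       sex_male = 0.10,
       race = c(black = -0.05, hispanic = -0.05, other = 0.00),
       comorbidity = cm,
       dx = dx,
       surgical = -0.20,
       ed_admission = 0.20,
       nursing_facility = 0.45,
       lab_z = labs)
}

# linear predictor of the true outcome model for a cohort data frame,
# excluding the hospital quality effect
outcome_linear_predictor <- function(df, coefficients) {
  co <- coefficients
  need <- c("intercept", "age_per_10y", "sex_male", "race", "comorbidity",
            "dx", "surgical", "ed_admission", "nursing_facility", "lab_z")
  miss <- setdiff(need, names(co))
  if (length(miss) > 0)
    stop("outcome coefficients missing block(s): ",
         paste(miss, collapse = ", "))
  lp <- rep(co$intercept, nrow(df))
  lp <- lp + co$age_per_10y * (df$age - 65) / 10
  lp <- lp + co$sex_male * (df$sex == "M")
  for (r in names(co$race)) lp <- lp + co$race[[r]] * (df$race_ethnicity == r)
  for (cmn in comorbidity_names())
    lp <- lp + co$comorbidity[[cmn]] * df[[paste0("cm_", cmn)]]
  dxv <- as.character(df$dx_category)
  dx_eff <- co$dx[dxv]
  dx_eff[is.na(dx_eff)] <- 0 # missing principal diagnosis: baseline risk
  lp <- lp + dx_eff
  lp <- lp + co$surgical * df$surgical + co$ed_admission * df$ed_admission +
    co$nursing_facility * df$nursing_facility
  ctr <- lab_center(); scl <- lab_scale()
  for (ln in lab_names())
    lp <- lp + co$lab_z[[ln]] * (df[[paste0("lab_", ln)]] - ctr[[ln]]) / scl[[ln]]
  unname(lp)
}

#' Simulate the 30-day mortality outcome for one hospitalization
#'
#' Draws death from Bernoulli(plogis(linear predictor + quality effect))
#' under the generating outcome model.
#'
#' @param record One-row data frame with the cohort covariate columns.
#' @param profile A `hospital_profile` (its `quality_effect` is added to the
#'   linear predictor).
#' @param coefficients Outcome-model coefficients,
#'   see [default_outcome_coefficients()].
#' @return Integer 0/1 draw, with the true probability in attribute `"prob"`.
#' @export
simulate_outcome <- function(record, profile,
                             coefficients = default_outcome_coefficients()) {
  stopifnot(nrow(record) == 1L)
  lp <- outcome_linear_predictor(record, coefficients) +
    profile$quality_effect
  p <- plogis(lp)
  structure(rbinom(1L, 1L, p), prob = p)
}

## ---- configuration and profiles ----------------------------------------

#' Configuration for the synthetic hospital system
#'
#' @param n_hospitals Number of hospitals (>= 2).
#' @param volume_range Annual admissions per hospital; volumes are drawn
#'   log-uniformly over this range to mimic the skew of real hospital
#'   systems.
#' @param heterogeneity Nonnegative scale multiplying every between-hospital
#'   case-mix difference; 0 gives identical case-mix at all hospitals.
#' @param quality_sd SD of the hospital quality effects (log-odds of 30-day
#'   mortality); 0 gives identical true quality.
#' @param coefficients True outcome-model coefficients.
#' @param psych_dominant Number of hospitals forced to >= 90% psychiatric /
#'   substance-abuse admissions (to exercise the exclusion cascade).
#' @param transfer_rate,transplant_rate,missing_dx_rate Marginal rates of
#'   within-system transfer rows, organ-transplant rows and missing
#'   principal diagnosis.
#' @return A `system_config` list.
#' @export
system_config <- function(n_hospitals = 40,
                          volume_range = c(300, 3000),
                          heterogeneity = 1,
                          quality_sd = 0.3,
                          coefficients = default_outcome_coefficients(),
                          psych_dominant = 0,
                          transfer_rate = 0.005,
                          transplant_rate = 0.0005,
                          missing_dx_rate = 0.0005) {
  if (n_hospitals < 2) stop("n_hospitals must be >= 2")
  if (any(volume_range <= 0)) stop("volumes must be positive")
  if (length(volume_range) != 2 || volume_range[2] < volume_range[1])
    stop("volume_range must be c(min, max) with max >= min")
  if (heterogeneity < 0) stop("heterogeneity scale must be >= 0")
  if (quality_sd < 0) stop("quality_sd must be >= 0")
  if (psych_dominant > n_hospitals)
    stop("psych_dominant exceeds n_hospitals")
  structure(list(n_hospitals = n_hospitals, volume_range = volume_range,
                 heterogeneity = heterogeneity, quality_sd = quality_sd,
                 coefficients = coefficients,
                 psych_dominant = psych_dominant,
                 transfer_rate = transfer_rate,
                 transplant_rate = transplant_rate,
                 missing_dx_rate = missing_dx_rate),
            class = "system_config")
}

# draw one hospital's case-mix parameter block; `het` scales all
# between-hospital spreads
draw_profile <- function(id, tier, volume, het, quality_sd, psych_dominant) {
  rl <- function(base, sdev) plogis(qlogis(base) + het * rnorm(1, 0, sdev))
  dirich <- function(base, conc) {
    if (het == 0) return(base)
    g <- rgamma(length(base), shape = base * conc / het)
    if (sum(g) == 0) return(base)
    setNames(g / sum(g), names(base))
  }
  race_p <- dirich(setNames(c(0.65, 0.20, 0.08, 0.07), race_levels()), 25)
  dx_p <- dirich(dx_base_prob(), 12)
  if (psych_dominant) {
    dx_p <- dx_p * (1 - 0.93) / sum(dx_p[names(dx_p) != "psych_substance"])
    dx_p["psych_substance"] <- 0.93
    dx_p <- dx_p / sum(dx_p)
  }
  structure(list(
    hospital_id = id,
    tier = tier,
    volume = volume,
    casemix = list(
      age_mean = 65 + het * rnorm(1, 0, 4),
      age_sd = 12,
      p_female = rl(0.06, 0.5),
      race_prob = race_p,
      comorbidity_prev = vapply(elix_base_prev(), rl, numeric(1),
                                sdev = 0.4),
      dx_prob = dx_p,
      p_surgical = rl(0.08, 1.0),
      p_ed = rl(0.60, 2.2),
      p_nursing = rl(0.04, 0.5),
      lab_shift = setNames(het * rnorm(11, 0, 0.15), lab_names())
    ),
    quality_effect = rnorm(1, 0, quality_sd)
  ), class = "hospital_profile")
}

validate_profile <- function(p) {
  stopifnot(p$volume >= 1, p$tier %in% 1:5)
  probs <- c(p$casemix$p_female, p$casemix$p_surgical, p$casemix$p_ed,
             p$casemix$p_nursing, p$casemix$comorbidity_prev,
             p$casemix$race_prob, p$casemix$dx_prob)
  stopifnot(all(probs >= 0 & probs <= 1))
  stopifnot(abs(sum(p$casemix$race_prob) - 1) < 1e-9,
            abs(sum(p$casemix$dx_prob) - 1) < 1e-9)
  invisible(p)
}

## ---- record generation --------------------------------------------------

# generate one hospital's rows from its profile (vectorized)
generate_hospital <- function(profile, config) {
  cm <- profile$casemix
  n <- profile$volume
  age <- pmin(pmax(rnorm(n, cm$age_mean, cm$age_sd), 18), 100)
  sex <- ifelse(runif(n) < cm$p_female, "F", "M")
  race <- sample(race_levels(), n, replace = TRUE, prob = cm$race_prob)
  dx <- sample(dx_categories(), n, replace = TRUE, prob = cm$dx_prob)
  ft <- fine_dx_table()
  fine <- character(n)
  for (cat in dx_categories()) {
    idx <- which(dx == cat)
    if (!length(idx)) next
    sub <- ft[ft$dx_category == cat, ]
    fine[idx] <- sample(sub$fine_dx_category, length(idx),
                        replace = TRUE, prob = sub$prob)
  }
  miss <- runif(n) < config$missing_dx_rate
  dx[miss] <- NA_character_
  fine[miss] <- NA_character_

  cmat <- vapply(cm$comorbidity_prev,
                 function(p) rbinom(n, 1L, p), integer(n))
  if (n == 1L) cmat <- matrix(cmat, nrow = 1,
                              dimnames = list(NULL, comorbidity_names()))
  colnames(cmat) <- paste0("cm_", comorbidity_names())

  surgical <- rbinom(n, 1L, cm$p_surgical)
  ed <- rbinom(n, 1L, cm$p_ed)
  nursing <- rbinom(n, 1L, cm$p_nursing)
  transfer <- rbinom(n, 1L, config$transfer_rate)
  transplant <- rbinom(n, 1L, config$transplant_rate)

  # labs: correlated z-scores + hospital shift + diagnosis shift
  z <- MASS::mvrnorm(n, mu = rep(0, 11), Sigma = lab_correlation())
  if (n == 1L) z <- matrix(z, nrow = 1)
  shift <- dx_lab_shift()[ifelse(is.na(dx), "other", dx), , drop = FALSE]
  z <- z + shift + matrix(cm$lab_shift, n, 11, byrow = TRUE)
  labs <- sweep(sweep(z, 2, lab_scale(), "*"), 2, lab_center(), "+")
  colnames(labs) <- paste0("lab_", lab_names())

  df <- data.frame(hospital_id = profile$hospital_id, tier = profile$tier,
                   age = age, sex = sex, race_ethnicity = race,
                   dx_category = dx, fine_dx_category = fine,
                   surgical = surgical, ed_admission = ed,
                   nursing_facility = nursing, transfer_from_va = transfer,
                   organ_transplant = transplant,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(cmat), as.data.frame(labs))
  lp <- outcome_linear_predictor(df, config$coefficients) +
    profile$quality_effect
  p <- plogis(lp)
  df$died_30d <- rbinom(n, 1L, p)
  df$predicted_mortality <- NA_real_
  attr(df, "true_prob") <- p
  df
}

#' Generate a synthetic multi-hospital system
#'
#' Draws hospital profiles (volume, tier, case-mix block, true quality
#' effect) and then one row per hospitalization from each profile. Hospital
#' volumes are log-uniform over `config$volume_range`; tiers 1-5 are
#' assigned by volume quintile (largest volumes = tier 1, mirroring the
#' association between size and critical-care capability). Each hospital's
#' rows are generated from a deterministic per-hospital substream of the
#' master seed, so results are reproducible row-for-row.
#'
#' @param config A [system_config()].
#' @param seed Integer master seed (required).
#' @return A list with `cohort` (a `cohort_table` data frame; the true
#'   per-row death probabilities are kept in attribute `"true_prob"`),
#'   `profiles` (list of `hospital_profile`), and `truth` (data frame of
#'   hospital id, tier, volume, quality effect).
#' @export
generate_system <- function(config = system_config(), seed) {
  if (missing(seed)) stop("seed must be given")
  stopifnot(inherits(config, "system_config"))
  set.seed(seed)
  H <- config$n_hospitals
  lv <- log(config$volume_range)
  volumes <- as.integer(round(exp(runif(H, lv[1], lv[2]))))
  tiers <- 6L - as.integer(cut(rank(volumes, ties.method = "first"),
                               breaks = 5, labels = FALSE))
  psych_ids <- if (config$psych_dominant > 0)
    sample(H, config$psych_dominant) else integer(0)
  ids <- sprintf("H%03d", seq_len(H))
  profiles <- vector("list", H)
  for (h in seq_len(H)) {
    profiles[[h]] <- draw_profile(ids[h], tiers[h], volumes[h],
                                  config$heterogeneity, config$quality_sd,
                                  h %in% psych_ids)
    validate_profile(profiles[[h]])
  }
  parts <- vector("list", H)
  probs <- vector("list", H)
  for (h in seq_len(H)) {
    set.seed(sub_seed(seed, h))
    parts[[h]] <- generate_hospital(profiles[[h]], config)
    probs[[h]] <- attr(parts[[h]], "true_prob")
  }
  cohort <- do.call(rbind, parts)
  rownames(cohort) <- NULL
  cohort <- as_cohort_table(cohort)
  attr(cohort, "true_prob") <- unlist(probs)
  truth <- data.frame(
    hospital_id = ids, tier = tiers, volume = volumes,
    quality_effect = vapply(profiles, `[[`, numeric(1), "quality_effect"))
  list(cohort = cohort, profiles = profiles, truth = truth)
}
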