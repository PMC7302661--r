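test_that("generation is deterministic under a fixed seed", {
  cfg <- system_config(n_hospitals = 4, volume_range = c(200, 500))
  a <- generate_system(cfg, seed = 77)
  b <- generate_system(cfg, seed = 77)
  expect_identical(as.data.frame(a$cohort), as.data.frame(b$cohort))
  expect_identical(a$truth, b$truth)
  c <- generate_system(cfg, seed = 78)
  expect_false(identical(as.data.frame(a$cohort), as.data.frame(c$cohort)))
})

test_that("invalid generator settings are rejected with messages", {
  expect_error(system_config(n_hospitals = 1), ">= 2")
  expect_error(system_config(volume_range = c(0, 100)), "positive")
  expect_error(system_config(heterogeneity = -1), ">= 0")
  expect_error(system_config(quality_sd = -0.1), ">= 0")
  expect_error(generate_system(system_config()), "seed")
})

test_that("per-hospital marginals track the profile parameters", {
  cfg <- system_config(n_hospitals = 2, volume_range = c(2000, 2001))
  gen <- generate_system(cfg, seed = 5)
  for (h in 1:2) {
    prof <- gen$profiles[[h]]
    rows <- gen$cohort[gen$cohort$hospital_id == prof$hospital_id, ]
    n <- nrow(rows)
    checks <- list(
      c(mean(rows$surgical), prof$casemix$p_surgical),
      c(mean(rows$ed_admission), prof$casemix$p_ed),
      c(mean(rows$sex == "F"), prof$casemix$p_female),
      c(mean(rows$cm_chf), prof$casemix$comorbidity_prev[["chf"]]),
      c(mean(rows$cm_depression),
        prof$casemix$comorbidity_prev[["depression"]]))
    for (ch in checks) {
      se <- sqrt(ch[2] * (1 - ch[2]) / n)
      expect_lt(abs(ch[1] - ch[2]), 3 * se + 1e-9)
    }
    # category probability vectors are simplexes
    expect_equal(sum(prof$casemix$dx_prob), 1, tolerance = 1e-9)
    expect_equal(sum(prof$casemix$race_prob), 1, tolerance = 1e-9)
  }
})

test_that("zero heterogeneity gives exchangeable hospitals (uniform KW p)", {
  cfg <- system_config(n_hospitals = 4, volume_range = c(150, 151),
                       heterogeneity = 0, quality_sd = 0)
  pvals <- vapply(1:300, function(r) {
    gen <- generate_system(cfg, seed = 1000 + r)
    kruskal.test(age ~ factor(hospital_id),
                 data = as.data.frame(gen$cohort))$p.value
  }, 1)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  # identical case-mix blocks across hospitals
  gen <- generate_system(cfg, seed = 4242)
  cm1 <- gen$profiles[[1]]$casemix
  for (h in 2:4) expect_equal(gen$profiles[[h]]$casemix, cm1)
})

test_that("with heterogeneity the between-hospital age test nearly always rejects", {
  cfg <- system_config(n_hospitals = 20, volume_range = c(1000, 1001))
  rejections <- vapply(1:8, function(r) {
    gen <- generate_system(cfg, seed = 3000 + r)
    kruskal.test(age ~ factor(hospital_id),
                 data = as.data.frame(gen$cohort))$p.value < 0.05
  }, TRUE)
  expect_gte(mean(rejections), 7 / 8)
})

test_that("pooled mortality matches the outcome model's marginal rate", {
  cfg <- system_config(n_hospitals = 20, volume_range = c(5000, 5001),
                       quality_sd = 0)
  gen <- generate_system(cfg, seed = 11)
  p <- attr(gen$cohort, "true_prob")
  n <- nrow(gen$cohort)
  expect_equal(length(p), n)
  # all quality effects are zero, so the observed rate must sit within
  # Monte-Carlo error of the model's average inverse-logit
  expect_true(all(gen$truth$quality_effect == 0))
  mc_se <- sqrt(mean(p * (1 - p)) / n)
  expect_lt(abs(mean(gen$cohort$died_30d) - mean(p)), 3 * mc_se)
})

test_that("simulate_outcome follows the logistic outcome model", {
  rec <- make_toy_cohort(1)
  prof <- structure(list(quality_effect = 0), class = "hospital_profile")
  zero <- default_outcome_coefficients()
  zero <- lapply(zero, function(b) b * 0)
  # all-zero coefficients: linear predictor 0, death probability 1/2
  expect_equal(attr(simulate_outcome(rec, prof, zero), "prob"), 0.5)
  # saturating quality effect
  prof$quality_effect <- 20
  expect_gt(attr(simulate_outcome(rec, prof, zero), "prob"), 0.999)
  # missing coefficient block is rejected
  expect_error(simulate_outcome(rec, prof, zero[-1]), "missing")

  # empirical odds ratio for a +1 quality effect is e (within 10%)
  set.seed(8)
  co <- default_outcome_coefficients()
  p0 <- attr(simulate_outcome(rec, structure(list(quality_effect = 0),
                                             class = "hospital_profile"),
                              co), "prob")
  p1 <- attr(simulate_outcome(rec, structure(list(quality_effect = 1),
                                             class = "hospital_profile"),
                              co), "prob")
  d0 <- rbinom(1e5, 1, p0); d1 <- rbinom(1e5, 1, p1)
  or <- (mean(d1) / (1 - mean(d1))) / (mean(d0) / (1 - mean(d0)))
  expect_lt(abs(or - exp(1)) / exp(1), 0.10)
})

test_that("psych-dominant hospitals and rare fine categories are generated", {
  cfg <- system_config(n_hospitals = 5, volume_range = c(500, 800),
                       psych_dominant = 2)
  gen <- generate_system(cfg, seed = 21)
  shares <- tapply(gen$cohort$dx_category == "psych_substance",
                   gen$cohort$hospital_id, mean, na.rm = TRUE)
  expect_equal(sum(shares > 0.9), 2)
  # the long-tailed fine categories leave something for the 1-in-300 rule
  expect_gt(length(rare_categories(gen$cohort)), 0)
  # lab correlation target is a valid covariance
  ev <- eigen(templatebench:::lab_correlation(), symmetric = TRUE,
              only.values = TRUE)$values
  expect_true(all(ev > 0))
})
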