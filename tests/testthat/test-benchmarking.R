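# build match_result-shaped objects directly, so ranking can be tested
# against hand-controlled matched samples
fake_match <- function(hospital_id, died, pred = 0.1) {
  m <- length(died)
  md <- data.frame(hospital_id = hospital_id, died_30d = died,
                   predicted_mortality = rep_len(pred, m))
  structure(list(hospital_id = hospital_id,
                 pairs = data.frame(template_index = seq_len(m),
                                    pool_index = seq_len(m)),
                 eligible = TRUE, feasible = TRUE, non_converged = FALSE,
                 matched_data = md),
            class = "match_result")
}

test_that("identical matched samples give equal estimates, deterministic ties", {
  set.seed(55)
  died <- rbinom(60, 1, 0.15)
  mr <- lapply(c("H1", "H2", "H3", "H4"), fake_match, died = died)
  names(mr) <- c("H1", "H2", "H3", "H4")
  rep <- rank_matched(mr)
  # equal up to the mixed-model convergence tolerance
  expect_lt(diff(range(rep$estimate)), 1e-5)
  expect_setequal(rep$rank, 1:4)
  expect_false(is.unsorted(rep$estimate))
})

test_that("a worse hospital is ranked worse and zero-death hospitals are ridged", {
  set.seed(56)
  good <- fake_match("GOOD", rbinom(200, 1, 0.05))
  bad <- fake_match("BAD", rbinom(200, 1, 0.30))
  none <- fake_match("NONE", rep(0L, 200))
  rep <- rank_matched(list(GOOD = good, BAD = bad, NONE = none))
  est <- setNames(rep$estimate, rep$hospital_id)
  expect_lt(est["GOOD"], est["BAD"])
  expect_lt(est["NONE"], est["GOOD"])
  expect_identical(attr(rep, "metadata")$ridged_hospitals, "NONE")
  expect_true(all(is.finite(rep$estimate)))
})

test_that("ineligible and non-converged hospitals are omitted from ranking", {
  set.seed(57)
  a <- fake_match("A", rbinom(100, 1, 0.1))
  b <- fake_match("B", rbinom(100, 1, 0.1))
  c <- fake_match("C", rbinom(100, 1, 0.1))
  c$non_converged <- TRUE
  d <- fake_match("D", rbinom(100, 1, 0.1))
  d$eligible <- FALSE; d$pairs <- NULL; d$matched_data <- NULL
  rep <- rank_matched(list(A = a, B = b, C = c, D = d))
  expect_setequal(rep$hospital_id, c("A", "B"))
  expect_setequal(attr(rep, "metadata")$omitted, c("C", "D"))
  expect_error(rank_matched(list(A = a, C = c)), "at least 2")
})

test_that("regression benchmark shrinks to zero under equal true quality", {
  cfg <- system_config(n_hospitals = 6, volume_range = c(600, 1200),
                       quality_sd = 0)
  gen <- generate_system(cfg, seed = 66)
  fit <- suppressWarnings(fit_risk_model(gen$cohort))
  rep <- rank_regression(fit$cohort)
  md <- attr(rep, "metadata")
  # no hospital's shrunken intercept may exceed 3 posterior SDs
  expect_true(all(abs(rep$estimate) <= 3 * rep$se + 1e-8) || md$singular)
  expect_identical(rep$rank, seq_len(nrow(rep)))
})

test_that("regression benchmark requires between-hospital contrast", {
  co <- make_toy_cohort(100, died_30d = rbinom(100, 1, 0.2),
                        predicted_mortality = 0.2)
  expect_error(rank_regression(co), ">= 2 hospitals")
})

test_that("quintile categories follow the ceiling rule", {
  mk <- function(H) data.frame(hospital_id = sprintf("H%03d", 1:H),
                               estimate = seq_len(H), rank = seq_len(H))
  c10 <- categorize(mk(10))
  expect_identical(as.vector(table(c10$category)), c(2L, 6L, 2L))
  c117 <- categorize(mk(117))
  expect_identical(as.vector(table(c117$category)), c(24L, 69L, 24L))
  expect_identical(c117$category[c117$rank == 1], factor("top",
    levels = c("top", "median", "bottom")))
  expect_error(categorize(mk(4)), "at least 5")
})

test_that("category assignment is invariant to hospital input order", {
  set.seed(58)
  # well-separated true quality, so categories are stable to optimizer
  # noise under row permutation
  cfg <- system_config(n_hospitals = 6, volume_range = c(400, 800),
                       quality_sd = 1.5)
  gen <- generate_system(cfg, seed = 67)
  fit <- suppressWarnings(fit_risk_model(gen$cohort))
  co <- fit$cohort
  perm <- as_cohort_table(as.data.frame(co)[sample(nrow(co)), ])
  r1 <- categorize(rank_regression(co))
  r2 <- categorize(rank_regression(perm))
  m <- match(r1$hospital_id, r2$hospital_id)
  expect_identical(as.character(r1$category), as.character(r2$category[m]))
})

test_that("ranking comparisons cross-tabulate categories and delegate to chi-square", {
  mk <- function(H, cats) {
    data.frame(hospital_id = sprintf("H%03d", 1:H),
               estimate = seq_len(H), rank = seq_len(H),
               category = factor(cats,
                                 levels = c("top", "median", "bottom")))
  }
  H <- 10
  a <- mk(H, rep(c("top", "median", "bottom"), c(2, 6, 2)))
  cmp_same <- compare_rankings(a, a)
  expect_true(all(cmp_same$table[upper.tri(cmp_same$table)] == 0))
  expect_equal(cmp_same$agreement, 1)

  b <- mk(H, rep(c("bottom", "median", "top"), c(2, 6, 2)))
  cmp <- compare_rankings(a, b)
  expect_equal(cmp$agreement, 0.6)
  oracle <- chi_square_independence(table(a$category, b$category))
  expect_equal(cmp$statistic, oracle$statistic)
  expect_equal(cmp$p_value, oracle$p_value)

  c_rep <- mk(H, rep(c("top", "median", "bottom"), c(2, 6, 2)))
  c_rep$hospital_id <- sprintf("X%03d", 1:H)
  expect_error(compare_rankings(a, c_rep), "no hospitals")
  expect_error(compare_rankings(a[, -4], b), "categorize")
})
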