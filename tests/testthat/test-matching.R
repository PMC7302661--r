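test_that("pair distance is Mahalanobis plus additive near-exact penalty", {
  set.seed(11)
  t_row <- data.frame(x1 = 1.2, x2 = -0.5, grp = "A")
  h_same <- t_row
  h_far <- data.frame(x1 = 0.2, x2 = 0.7, grp = "B")
  cov <- matrix(c(1, 0.3, 0.3, 2), 2)
  spec <- match_spec(distance_roster = c("x1", "x2"), near_exact = "grp",
                     fine_balance = NULL, penalty = 50)
  expect_equal(pair_distance(t_row, h_same, spec, cov), 0)
  d <- c(1.2 - 0.2, -0.5 - 0.7)
  expect_equal(pair_distance(t_row, h_far, spec, cov),
               sqrt(drop(t(d) %*% solve(cov) %*% d)) + 50)
  h_mismatch_only <- data.frame(x1 = 1.2, x2 = -0.5, grp = "B")
  expect_equal(pair_distance(t_row, h_mismatch_only, spec, cov), 50)
})

test_that("unconstrained solver attains the exhaustive-search optimum", {
  set.seed(21)
  spec <- match_spec(distance_roster = c("x1", "x2"), near_exact = NULL,
                     fine_balance = NULL, ratio = 1L)
  cov <- diag(2)
  for (rep in 1:60) {
    m <- sample(2:6, 1); n <- sample(m:10, 1)
    inst <- random_match_instance(m, n)
    res <- optimal_match(inst$template, inst$pool, spec, cov)
    Xt <- as.matrix(inst$template); Xp <- as.matrix(inst$pool)
    C <- as.matrix(dist(rbind(Xt, Xp)))[seq_len(m), m + seq_len(n),
                                        drop = FALSE]
    expect_true(res$feasible)
    expect_equal(res$total_distance, dp_min_assignment(C), tolerance = 1e-8)
    # pairs form an injection
    expect_equal(length(unique(res$pairs$pool_index)), m)
  }
})

test_that("solver agrees with the Hungarian algorithm on square instances", {
  skip_if_not_installed("clue")
  set.seed(31)
  spec <- match_spec(distance_roster = c("x1", "x2"), near_exact = NULL,
                     fine_balance = NULL, ratio = 1L)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    inst <- random_match_instance(n, n)
    res <- optimal_match(inst$template, inst$pool, spec, diag(2))
    C <- as.matrix(dist(rbind(as.matrix(inst$template),
                              as.matrix(inst$pool))))[seq_len(n),
                                                      n + seq_len(n)]
    lsap <- clue::solve_LSAP(C)
    expect_equal(res$total_distance, sum(C[cbind(seq_len(n), lsap)]),
                 tolerance = 1e-7)
  }
})

test_that("a pool containing exact copies of the template matches at zero", {
  set.seed(41)
  inst <- random_match_instance(5, 5, n_cat = 2)
  pool <- rbind(inst$template, inst$pool)
  spec <- match_spec(distance_roster = c("x1", "x2"), near_exact = "grp",
                     fine_balance = "grp", ratio = 2L)
  res <- optimal_match(inst$template, pool, spec, diag(2))
  expect_true(res$feasible)
  expect_equal(res$total_distance, 0)
  expect_equal(unname(res$near_exact_mismatches["grp"]), 0L)
  expect_true(all(unlist(res$fine_balance_satisfied)))
})

test_that("fine balance holds exactly when reported, and binds otherwise", {
  # template {A:2, B:2}, pool {A:1, B:5}: only one A available
  t_rows <- data.frame(x1 = c(0, 0, 1, 1), grp = c("A", "A", "B", "B"))
  p_rows <- data.frame(x1 = rnorm(6), grp = c("A", rep("B", 5)))
  spec <- match_spec(distance_roster = "x1", near_exact = NULL,
                     fine_balance = "grp", ratio = 1L)
  res <- optimal_match(t_rows, p_rows, spec, matrix(1))
  expect_false(res$feasible)
  expect_identical(res$binding_variable, "grp")
  expect_false(res$fine_balance_satisfied[["grp"]])
  chk <- check_fine_balance(res, "grp")
  expect_false(chk$satisfied)
  # deficits are reciprocal: +1 B for the missing A
  expect_equal(sum(chk$deficits$deficit), 0L)
  expect_equal(chk$deficits$deficit[chk$deficits$category == "A"], -1L)

  # attainable case: counts match exactly (integer equality)
  p_ok <- data.frame(x1 = rnorm(8),
                     grp = c("A", "A", "A", "B", "B", "B", "B", "B"))
  res2 <- optimal_match(t_rows, p_ok, spec, matrix(1))
  expect_true(res2$feasible)
  expect_identical(table(res2$matched_data$grp),
                   table(c("A", "A", "B", "B")))
})

test_that("adding a fine-balance constraint never decreases total distance", {
  set.seed(51)
  for (rep in 1:40) {
    m <- sample(3:6, 1)
    nn <- (2 * m):10; n <- nn[sample.int(length(nn), 1)]
    inst <- random_match_instance(m, n, n_cat = 2)
    free_spec <- match_spec(distance_roster = c("x1", "x2"),
                            near_exact = NULL, fine_balance = NULL,
                            ratio = 1L)
    fb_spec <- match_spec(distance_roster = c("x1", "x2"),
                          near_exact = NULL, fine_balance = "grp",
                          ratio = 1L)
    free <- optimal_match(inst$template, inst$pool, free_spec, diag(2))
    cons <- optimal_match(inst$template, inst$pool, fb_spec, diag(2))
    expect_gte(cons$total_distance, free$total_distance - 1e-9)
    if (cons$feasible) {
      chk <- check_fine_balance(cons, "grp")
      expect_true(chk$satisfied)
      expect_true(all(chk$deficits$deficit == 0L))
    }
  }
})

test_that("near-exact agreement is lexicographic when exactly feasible", {
  set.seed(61)
  for (rep in 1:20) {
    m <- 4; n <- 8
    inst <- random_match_instance(m, n, n_cat = 2)
    # guarantee a zero-mismatch assignment exists
    inst$pool$grp[seq_len(m)] <- inst$template$grp
    spec <- match_spec(distance_roster = c("x1", "x2"),
                       near_exact = "grp", fine_balance = NULL, ratio = 2L)
    res <- optimal_match(inst$template, inst$pool, spec, diag(2))
    expect_equal(unname(res$near_exact_mismatches["grp"]), 0L)
  }
})

test_that("layered fine balance prioritises the first variable", {
  set.seed(71)
  # second-layer balance impossible, first layer attainable
  t_rows <- data.frame(x1 = rnorm(4), g1 = c("A", "A", "B", "B"),
                       g2 = c("u", "v", "u", "v"))
  p_rows <- data.frame(x1 = rnorm(8), g1 = rep(c("A", "B"), each = 4),
                       g2 = "u")
  spec <- match_spec(distance_roster = "x1", near_exact = NULL,
                     fine_balance = c("g1", "g2"), ratio = 2L)
  res <- optimal_match(t_rows, p_rows, spec, matrix(1))
  expect_true(res$fine_balance_satisfied[["g1"]])
  expect_false(res$fine_balance_satisfied[["g2"]])
  expect_identical(res$binding_variable, "g2")
  expect_false(res$feasible)
})

test_that("pools below the matching ratio are flagged ineligible", {
  inst <- random_match_instance(4, 8)
  spec <- match_spec(distance_roster = c("x1", "x2"), near_exact = NULL,
                     fine_balance = NULL, ratio = 3L)
  res <- optimal_match(inst$template, inst$pool, spec, diag(2))
  expect_false(res$eligible)
  expect_null(res$pairs)
})

test_that("exceeding the network budget reports non-convergence", {
  inst <- random_match_instance(6, 12)
  spec <- match_spec(distance_roster = c("x1", "x2"), near_exact = NULL,
                     fine_balance = NULL, ratio = 2L, arc_budget = 10)
  res <- optimal_match(inst$template, inst$pool, spec, diag(2))
  expect_true(res$non_converged)
  expect_false(res$feasible)
})

test_that("sparse network thinning preserves exact fine balance", {
  sys <- small_eligible_system()
  el <- sys$eligible
  tmpl <- select_template(el, draw_candidates(el, 60, 5, seed = 5))
  spec_sparse <- match_spec(sparse_neighbors = 10)
  spec_dense <- match_spec()
  h <- unique(el$hospital_id)[1]
  pool <- el[el$hospital_id == h, ]
  cov <- pooled_covariance(el, spec_dense$distance_roster)
  rs <- optimal_match(tmpl, pool, spec_sparse, cov)
  rd <- optimal_match(tmpl, pool, spec_dense, cov)
  expect_equal(rs$feasible, rd$feasible)
  if (rd$feasible) {
    expect_true(all(unlist(rs$fine_balance_satisfied)))
    # thinning is allowed to cost a little distance, never balance
    expect_gte(rs$total_distance, rd$total_distance - 1e-9)
  }
})
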