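test_that("exact cross-match null matches full pairing enumeration", {
  for (sizes in list(c(2, 2), c(3, 3), c(4, 4), c(5, 5), c(6, 6),
                     c(4, 6), c(3, 5))) {
    m <- sizes[1]; n <- sizes[2]
    pmf <- crossmatch_null_pmf(m, n)
    expect_equal(sum(pmf$prob), 1, tolerance = 1e-12)
    # parity: attainable counts share the parity of the group sizes
    expect_true(all((pmf$a1 - m) %% 2 == 0))
    grp <- rep(c(0L, 1L), c(m, n))
    ps <- all_pairings(m + n)
    cc <- vapply(ps, cross_count, 1L, grp = grp)
    enum <- table(cc) / length(ps)
    expect_equal(pmf$prob, as.numeric(enum[as.character(pmf$a1)]),
                 tolerance = 1e-12)
  }
})

test_that("cross-match detects separated groups and accepts interleaved ones", {
  # two tight same-group clusters: no cross pairs, p = P(A1 = 0) = 1/3
  template <- data.frame(x1 = c(0, 0.1), x2 = 0)
  hosp <- data.frame(x1 = c(10, 10.1), x2 = 10)
  res <- crossmatch_test(template, hosp, roster = c("x1", "x2"),
                         cov = diag(2))
  expect_equal(res$a1, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  # 1/3 is the smallest attainable p at n = 2: not flagged at 0.05
  expect_false(res$poorly_matched)

  # perfectly interleaved groups: every pair crosses, p = 1
  n <- 5
  template <- data.frame(x1 = 2 * (0:(n - 1)), x2 = 0)
  hosp <- data.frame(x1 = 2 * (0:(n - 1)) + 0.001, x2 = 0)
  res <- crossmatch_test(template, hosp, roster = c("x1", "x2"),
                         cov = diag(2))
  expect_equal(res$a1, n)
  expect_equal(res$p_value, 1)
  expect_false(res$poorly_matched)
})

test_that("exact null for n = 4 agrees with Monte-Carlo random pairings", {
  set.seed(99)
  m <- 4; n <- 4
  pmf <- crossmatch_null_pmf(m, n)
  grp <- rep(c(0L, 1L), c(m, n))
  B <- 20000
  cc <- vapply(seq_len(B), function(b) {
    perm <- sample.int(m + n)
    cross_count(matrix(perm, ncol = 2, byrow = TRUE), grp)
  }, 1L)
  emp <- as.numeric(table(factor(cc, levels = pmf$a1))) / B
  se <- sqrt(pmf$prob * (1 - pmf$prob) / B)
  expect_true(all(abs(emp - pmf$prob) < 4 * se + 1e-12))
})

test_that("blossom matching attains the enumerated optimum and beats greedy", {
  set.seed(7)
  insts <- lapply(1:12, function(i) {
    n2 <- 2 * sample(2:6, 1)
    X <- matrix(rnorm(n2 * 2), n2)
    D <- as.matrix(dist(X))
    D
  })
  pairings <- min_weight_perfect_matching(insts)
  for (i in seq_along(insts)) {
    D <- insts[[i]]
    got <- sum(D[pairings[[i]]])
    oracle <- enum_min_matching(D)
    expect_equal(got, oracle$weight, tolerance = 1e-9)
    expect_lte(got, pairing_weight(D, greedy_pairing(D)) + 1e-9)
    # pairing is perfect: every subject appears exactly once
    expect_setequal(as.vector(pairings[[i]]), seq_len(nrow(D)))
  }
})

test_that("cross-match count parity follows the group sizes", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    template <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    hosp <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    res <- crossmatch_test(template, hosp, roster = c("x1", "x2"),
                           cov = diag(2))
    expect_equal((res$a1 - n) %% 2, 0)
    expect_gte(res$p_value, 0)
    expect_lte(res$p_value, 1)
  }
})

test_that("normal approximation is close to the exact tail at n = 40", {
  pmf <- crossmatch_null_pmf(40, 40)
  for (a1 in c(28, 32, 36)) {
    exact <- sum(pmf$prob[pmf$a1 <= a1])
    mu <- 40 * 40 / 79
    v <- 2 * 40 * 39 * 40 * 39 / (77 * 79^2)
    approx <- pnorm((a1 + 1 - mu) / sqrt(v))
    expect_equal(approx, exact, tolerance = 0.15)
  }
})

test_that("Kruskal-Wallis wrapper reproduces the hand-derived statistic", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(r$df, 1)
  expect_identical(r$status, "ok")

  r2 <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_gt(r2$p_value, 0.9)

  r3 <- kruskal_wallis(list(rep(5, 4), rep(5, 3)))
  expect_identical(r3$status, "degenerate")
  expect_true(is.na(r3$statistic))

  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("chi-square wrapper follows the Pearson formula", {
  r <- chi_square_independence(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r2 <- chi_square_independence(matrix(c(20, 10, 10, 20), 2))
  expect_equal(r2$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(r2$df, 1)

  # doubling every cell doubles the statistic
  r4 <- chi_square_independence(2 * matrix(c(20, 10, 10, 20), 2))
  expect_equal(r4$statistic, 2 * r2$statistic, tolerance = 1e-12)

  expect_warning(
    r5 <- chi_square_independence(matrix(c(5, 0, 7, 0, 0, 0, 3, 0, 4), 3)),
    "zero-marginal")
  expect_identical(r5$df, 1L)
})

test_that("balance table audits every roster variable across hospitals", {
  set.seed(123)
  mk <- function(shift = 0, n = 120) {
    data.frame(age = rnorm(n, 65 + shift, 10),
               sex = sample(c("F", "M"), n, replace = TRUE),
               surgical = rbinom(n, 1, 0.2))
  }
  same <- list(A = mk(), B = mk(), C = mk())
  rep1 <- balance_table(same, roster = c("age", "sex", "surgical"),
                        threshold = 0.05)
  expect_equal(nrow(rep1), 3)
  expect_true(all(c("variable", "p_value", "balanced") %in% names(rep1)))

  shifted <- list(A = mk(), B = mk(), C = mk(shift = 20))
  rep2 <- balance_table(shifted, roster = c("age", "sex", "surgical"))
  expect_false(rep2$balanced[rep2$variable == "age"])

  # identical matched samples: every non-degenerate variable balanced
  ident <- list(A = mk(n = 80), B = NULL)
  ident$B <- ident$A
  rep3 <- balance_table(ident, roster = c("age", "sex", "surgical"))
  expect_true(all(rep3$balanced))

  const <- list(A = data.frame(z = rep(1, 10)),
                B = data.frame(z = rep(1, 10)))
  expect_warning(rep4 <- balance_table(const, roster = "z"), "constant")
  expect_identical(rep4$status, "degenerate")
  expect_true(rep4$balanced)
})
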