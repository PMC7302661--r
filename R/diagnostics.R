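#' @name match_diagnostics
#' @title Match-quality diagnostics
#'
#' @description
#' Two audits of match quality. The cross-match test pools the template
#' cases with one hospital's matched sample, divides the pooled subjects
#' into pairs minimizing total Mahalanobis distance (exact non-bipartite
#' minimum-weight perfect matching), and counts pairs with one member from
#' each group; few cross pairs indicate the two groups occupy different
#' regions of covariate space, and the p-value comes from the exact
#' permutation null over all pairings (normal approximation for large
#' groups). Omnibus balance tests compare each matching variable across all
#' hospitals' matched samples with Kruskal-Wallis (continuous) or Pearson
#' chi-square (categorical) tests.
NULL

## ---- exact minimum-weight perfect matching ------------------------------

find_python <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("no python interpreter found on PATH (required for the ",
       "minimum-weight perfect matching backend)")
}

#' Exact minimum-weight perfect matching of an even set of subjects
#'
#' Solves the general (non-bipartite) minimum-weight perfect matching
#' problem exactly via the blossom algorithm (delegated to the networkx
#' implementation through a batched subprocess). Accepts one distance
#' matrix or a list of them; batching amortises interpreter start-up when
#' many instances are solved, e.g. in permutation studies.
#'
#' @param d A symmetric distance matrix with an even number of rows, or a
#'   list of such matrices.
#' @return A two-column matrix of 1-based index pairs (or a list of them),
#'   one row per pair.
#' @export
min_weight_perfect_matching <- function(d) {
  single <- is.matrix(d)
  if (single) d <- list(d)
  for (x in d) {
    if (!is.matrix(x) || nrow(x) != ncol(x) || nrow(x) %% 2 != 0)
      stop("each instance must be a square matrix of even dimension")
    if (any(!is.finite(x))) stop("non-finite distances")
  }
  script <- system.file("python", "mwpm.py", package = "templatebench")
  if (script == "") stop("bundled mwpm.py not found")
  payload <- lapply(d, function(x)
    list(n = nrow(x), d = as.vector(t(x))))
  infile <- tempfile(fileext = ".json")
  on.exit(unlink(infile), add = TRUE)
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA)
  out <- system2(find_python(), shQuote(script), stdout = TRUE,
                 stdin = infile)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("matching backend failed with status ", status)
  res <- jsonlite::fromJSON(paste(out, collapse = ""),
                            simplifyMatrix = TRUE)
  if (is.array(res) && length(dim(res)) == 3) { # uniform batch
    res <- lapply(seq_len(dim(res)[1]), function(i) res[i, , ])
  }
  res <- lapply(res, function(p) matrix(as.integer(p), ncol = 2) + 1L)
  if (single) res[[1]] else res
}

## ---- cross-match test ---------------------------------------------------

# log double factorial of an odd integer x >= -1, with (-1)!! = 1
ldfact_odd <- function(x) {
  k <- (x + 1) / 2
  lgamma(2 * k + 1) - k * log(2) - lgamma(k + 1)
}

#' Exact null distribution of the cross-match count
#'
#' Probability mass of A1 (number of cross-group pairs) when all pairings
#' of the pooled m + n subjects are equally likely:
#' `P(A1 = a) = C(m,a) C(n,a) a! (m-a-1)!! (n-a-1)!! / (m+n-1)!!`,
#' supported on a with the parity of m (and n).
#'
#' @param m,n Group sizes; `m + n` must be even.
#' @return Data frame with `a1` and `prob` over the attainable values.
#' @export
crossmatch_null_pmf <- function(m, n) {
  if ((m + n) %% 2 != 0) stop("combined size must be even")
  a <- seq.int(min(m, n), 0, by = -2)
  if (length(a) == 0 || (m - a[1]) %% 2 != 0)
    stop("no attainable cross-match count for these group sizes")
  lp <- lchoose(m, a) + lchoose(n, a) + lgamma(a + 1) +
    ldfact_odd(m - a - 1) + ldfact_odd(n - a - 1) - ldfact_odd(m + n - 1)
  data.frame(a1 = rev(a), prob = rev(exp(lp)))
}

#' Cross-match test of a hospital's match to the template
#'
#' @param template_rows Template cases (data frame).
#' @param matched_rows The hospital's matched sample (data frame, same
#'   columns).
#' @param roster Variables entering the pooled Mahalanobis distance
#'   (typically the matching roster).
#' @param cov Covariance for the distance metric; default: covariance of
#'   the pooled design (pseudo-inverse handles singularity).
#' @param threshold `poorly_matched` flag cut on the p-value
#'   (default 0.05).
#' @param exact_max Use the exact null for group sizes up to this value,
#'   the normal approximation (with continuity correction) above
#'   (default 30).
#' @param pairing Optional precomputed pairing (two-column index matrix
#'   over the pooled subjects, template first); when omitted the exact
#'   minimum-distance pairing is computed.
#' @return A `crossmatch_result`: `a1`, `n_pairs`, `p_value`,
#'   `poorly_matched`, `expected_a1`.
#' @export
crossmatch_test <- function(template_rows, matched_rows,
                            roster = default_match_roster(), cov = NULL,
                            threshold = 0.05, exact_max = 30,
                            pairing = NULL) {
  m <- nrow(template_rows); n <- nrow(matched_rows)
  if (m == 0 || n == 0) stop("both groups must be nonempty")
  if ((m + n) %% 2 != 0) stop("combined size must be even")
  pooled <- rbind(as.data.frame(template_rows)[,
                    intersect(names(template_rows), names(matched_rows))],
                  as.data.frame(matched_rows)[,
                    intersect(names(template_rows), names(matched_rows))])
  X <- roster_design(pooled, roster)
  if (is.null(cov)) cov <- cov(X)
  if (is.null(pairing)) {
    D <- mahal_cross_distance(X, X, cov)
    diag(D) <- 0
    pairing <- min_weight_perfect_matching(D)
  }
  grp <- rep(c(0L, 1L), c(m, n))
  a1 <- sum(grp[pairing[, 1]] != grp[pairing[, 2]])
  if (max(m, n) <= exact_max) {
    pmf <- crossmatch_null_pmf(m, n)
    p <- sum(pmf$prob[pmf$a1 <= a1])
  } else {
    N <- m + n
    mu <- m * n / (N - 1)
    v <- 2 * m * (m - 1) * n * (n - 1) / ((N - 3) * (N - 1)^2)
    # support has step 2, hence a continuity correction of 1
    p <- pnorm((a1 + 1 - mu) / sqrt(v))
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(a1 = a1, n_pairs = nrow(pairing), p_value = p,
                 poorly_matched = p < threshold,
                 expected_a1 = m * n / (m + n - 1),
                 pairing = pairing),
            class = "crossmatch_result")
}

#' @export
print.crossmatch_result <- function(x, ...) {
  cat(sprintf(
    "<crossmatch> a1 = %d of %d pairs (null mean %.1f), p = %.4g%s\n",
    x$a1, x$n_pairs, x$expected_a1, x$p_value,
    if (x$poorly_matched) " [poorly matched]" else ""))
  invisible(x)
}

## ---- univariate balance tests -------------------------------------------

#' Kruskal-Wallis rank test across groups
#'
#' Mid-rank H statistic with tie correction (via [stats::kruskal.test()]),
#' with an explicit degenerate status when every value is identical (the
#' tie-corrected statistic is 0/0 there).
#'
#' @param groups List of >= 2 nonempty numeric vectors.
#' @return List: `statistic`, `df`, `p_value`, `status`
#'   (`"ok"`/`"degenerate"`; statistic is `NA` when degenerate).
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) == 0)) stop("empty group")
  x <- unlist(groups)
  if (length(unique(x)) == 1)
    return(list(statistic = NA_real_, df = length(groups) - 1L,
                p_value = NA_real_, status = "degenerate"))
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  kt <- kruskal.test(x, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, status = "ok")
}

#' Pearson chi-square test of independence on a count table
#'
#' Zero-marginal rows/columns are dropped with a warning; no continuity
#' correction.
#'
#' @param table An r x c matrix of nonnegative counts.
#' @return List: `statistic`, `df`, `p_value`, `status`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  keep_r <- rowSums(table) > 0; keep_c <- colSums(table) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-marginal row(s)/column(s)")
    table <- table[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(table) < 2 || ncol(table) < 2)
    return(list(statistic = NA_real_, df = NA_integer_,
                p_value = NA_real_, status = "degenerate"))
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, status = "ok")
}

## ---- omnibus balance table ----------------------------------------------

#' Omnibus balance of matching variables across matched samples
#'
#' One test per roster variable across all hospitals' matched samples:
#' Kruskal-Wallis for continuous variables, Pearson chi-square for
#' categorical/binary ones. A variable is balanced when its p-value is at
#' least `threshold`; constant variables are marked degenerate-balanced
#' with a warning.
#'
#' @param matched_samples Named list (by hospital) of matched-row data
#'   frames, e.g. `lapply(results, function(r) r$matched_data)`.
#' @param roster Variables to audit.
#' @param threshold Balance cut on the p-value (default 0.05).
#' @return A `balance_report` data frame: variable, test, statistic,
#'   p_value, balanced, status; summary counts in attributes
#'   `n_balanced` / `n_unbalanced`.
#' @export
balance_table <- function(matched_samples, roster = default_match_roster(),
                          threshold = 0.05) {
  if (length(matched_samples) < 2) stop("need >= 2 hospitals")
  stacked <- do.call(rbind, lapply(names(matched_samples), function(h) {
    d <- as.data.frame(matched_samples[[h]])
    d$.hospital <- h
    d
  }))
  rows <- lapply(roster, function(v) {
    x <- stacked[[v]]
    if (is.null(x)) stop("roster variable not found: ", v)
    continuous <- is.numeric(x) && length(unique(x)) > 10
    if (length(unique(x)) == 1) {
      warning("variable '", v, "' is constant; marked degenerate-balanced")
      return(data.frame(variable = v, test = NA_character_,
                        statistic = NA_real_, p_value = NA_real_,
                        balanced = TRUE, status = "degenerate"))
    }
    if (continuous) {
      r <- kruskal_wallis(split(x, stacked$.hospital))
      test <- "kruskal_wallis"
    } else {
      r <- chi_square_independence(table(stacked$.hospital, x))
      test <- "chi_square"
    }
    balanced <- if (r$status == "ok") r$p_value >= threshold else TRUE
    data.frame(variable = v, test = test, statistic = r$statistic,
               p_value = r$p_value, balanced = balanced, status = r$status)
  })
  rep <- do.call(rbind, rows)
  class(rep) <- c("balance_report", "data.frame")
  attr(rep, "threshold") <- threshold
  attr(rep, "n_balanced") <- sum(rep$balanced)
  attr(rep, "n_unbalanced") <- sum(!rep$balanced)
  rep
}

#' Stacked-bar summary of balanced vs unbalanced variables per run
#'
#' @param reports Named list of `balance_report`s (one per matching run).
#' @param ... Passed to [graphics::barplot()].
#' @return The count matrix, invisibly.
#' @export
plot_balance_summary <- function(reports, ...) {
  counts <- vapply(reports, function(r)
    c(balanced = sum(r$balanced), unbalanced = sum(!r$balanced)),
    numeric(2))
  graphics::barplot(counts, legend.text = TRUE,
                    col = c("turquoise3", "orange2"),
                    ylab = "matching variables", ...)
  invisible(counts)
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report> %d balanced, %d unbalanced (p >= %.2f)\n",
              attr(x, "n_balanced"), attr(x, "n_unbalanced"),
              attr(x, "threshold")))
  print(as.data.frame(x))
  invisible(x)
}
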