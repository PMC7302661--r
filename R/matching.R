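#' @name matching_engine
#' @title Optimal 1:1 matching to the template
#'
#' @description
#' For each hospital, finds the minimum-total-distance 1:1 assignment of m
#' of its hospitalizations to the m template cases. The pair distance is
#' the Mahalanobis distance over a distance roster (pooled-cohort
#' covariance, pseudo-inverse) plus a large penalty per mismatched
#' near-exact variable, which makes near-exact agreement lexicographically
#' dominant over distance. Fine-balance constraints - the matched sample's
#' category distribution must equal the template's exactly - are encoded as
#' capacitated category layers in a min-cost-flow network (priority
#' layering: the first fine-balance variable is balanced most strictly,
#' later ones subject to earlier layers via category interactions).
#' Unattainable balance and solver budget overruns are reported, never
#' silently dropped.
NULL

#' Default matching roster (high-prognostic-significance set)
#'
#' Predicted mortality, age, sex, admission source (emergency department),
#' seven major comorbidities, surgical indicator, and broad
#' principal-diagnosis category.
#'
#' @return Character vector of roster entries.
#' @export
default_match_roster <- function() {
  c("predicted_mortality", "age", "sex", "ed_admission",
    paste0("cm_", c("chf", "chronic_pulm", "paralysis", "renal_failure",
                    "liver_disease", "mets_cancer", "depression")),
    "surgical", "dx_category")
}

#' Specification of one matching run
#'
#' @param distance_roster Variables entering the Mahalanobis pair distance.
#' @param near_exact Variables preferring exact within-pair agreement
#'   (penalty-based, ordered; a variable may also appear in the distance
#'   roster).
#' @param fine_balance Categorical variables whose matched-sample
#'   distribution must equal the template's exactly, in priority order.
#' @param penalty Near-exact mismatch penalty; default
#'   `(m + 1) * max(base distance)`, recomputed per hospital, which makes
#'   near-exact agreement dominate any achievable total distance.
#' @param ratio Required pool-to-template ratio for eligibility (default 3).
#' @param sparse_neighbors If not `NULL`, each template case is connected
#'   only to its `sparse_neighbors` nearest pool rows (network thinning for
#'   large pools); the solver falls back towards a dense network whenever
#'   the thinned network is infeasible.
#' @param node_budget,arc_budget Solver size budgets; a network exceeding
#'   either is reported as non-converged rather than solved.
#' @return A `match_spec` list.
#' @export
match_spec <- function(distance_roster = default_match_roster(),
                       near_exact = "surgical",
                       fine_balance = "dx_category",
                       penalty = NULL, ratio = 3L,
                       sparse_neighbors = NULL,
                       node_budget = 1e5, arc_budget = 2e6) {
  if (!is.null(penalty) && penalty <= 0) stop("penalty must be positive")
  if (ratio < 1) stop("ratio must be >= 1")
  structure(list(distance_roster = distance_roster,
                 near_exact = near_exact %||% character(0),
                 fine_balance = fine_balance %||% character(0),
                 penalty = penalty, ratio = as.integer(ratio),
                 sparse_neighbors = sparse_neighbors,
                 node_budget = node_budget, arc_budget = arc_budget),
            class = "match_spec")
}

#' Pooled covariance of the distance roster
#'
#' @param cohort Eligible `cohort_table` (the pooled population).
#' @param roster Distance roster.
#' @return Covariance matrix over the roster design columns.
#' @export
pooled_covariance <- function(cohort, roster = default_match_roster()) {
  cov(roster_design(cohort, roster))
}

# m x n matrix of Mahalanobis distances between template design rows and
# pool design rows, via the pseudo-inverse metric
mahal_cross_distance <- function(Xt, Xp, cov) {
  M <- MASS::ginv(as.matrix(cov))
  A <- Xt %*% M
  D2 <- matrix(rowSums(A * Xt), nrow(Xt), nrow(Xp)) +
    matrix(rowSums((Xp %*% M) * Xp), nrow(Xt), nrow(Xp), byrow = TRUE) -
    2 * tcrossprod(A, Xp)
  sqrt(pmax(D2, 0))
}

# count of mismatched near-exact variables for every template x pool pair
near_exact_mismatch_matrix <- function(t_rows, p_rows, near_exact) {
  m <- nrow(t_rows); n <- nrow(p_rows)
  M <- matrix(0L, m, n)
  for (v in near_exact) {
    tv <- t_rows[[v]]; pv <- p_rows[[v]]
    M <- M + outer(tv, pv, "!=")
  }
  M
}

#' Distance between one template case and one hospitalization
#'
#' Mahalanobis distance over the distance roster plus
#' `penalty * number of mismatched near-exact variables`.
#'
#' @param t_row,h_row One-row data frames.
#' @param spec A [match_spec()] (its `penalty` must be set).
#' @param cov Pooled covariance from [pooled_covariance()].
#' @return Nonnegative scalar.
#' @export
pair_distance <- function(t_row, h_row, spec, cov) {
  stopifnot(nrow(t_row) == 1L, nrow(h_row) == 1L)
  both <- rbind(as.data.frame(t_row), as.data.frame(h_row))
  X <- roster_design(both, spec$distance_roster)
  d <- mahal_cross_distance(X[1, , drop = FALSE], X[2, , drop = FALSE], cov)
  mm <- near_exact_mismatch_matrix(t_row, h_row, spec$near_exact)
  pen <- spec$penalty
  if (is.null(pen)) pen <- 0
  drop(d) + pen * drop(mm)
}

# interaction labels for fine-balance priority layers 1..L
fb_layer_labels <- function(rows, fine_balance) {
  L <- length(fine_balance)
  out <- vector("list", L)
  acc <- NULL
  for (l in seq_len(L)) {
    v <- as.character(rows[[fine_balance[l]]])
    acc <- if (is.null(acc)) v else paste(acc, v, sep = "\r")
    out[[l]] <- acc
  }
  out
}

#' Optimally match one hospital's hospitalizations to the template
#'
#' @param template A `template` object (or data frame of template rows).
#' @param hospital_rows `cohort_table` rows of one hospital (the pool).
#' @param spec A [match_spec()].
#' @param cov Pooled covariance of the distance roster; computed from the
#'   combined template + pool rows when omitted (the pipeline passes the
#'   eligible-cohort covariance).
#' @return A `match_result`: `pairs` (template index, pool row index),
#'   `total_distance` (base Mahalanobis total), `eligible`, `feasible`,
#'   `non_converged`, `fine_balance_satisfied` (per variable),
#'   `binding_variable`, `near_exact_mismatches` (per variable),
#'   `penalty`, plus the matched rows.
#' @export
optimal_match <- function(template, hospital_rows, spec = match_spec(),
                          cov = NULL) {
  t_rows <- if (inherits(template, "template")) template$data else template
  t_rows <- as.data.frame(t_rows)
  p_rows <- as.data.frame(hospital_rows)
  # deterministic network construction: pool sorted by original order is
  # preserved; ties among optima break by the solver's arc ordering
  m <- nrow(t_rows); n <- nrow(p_rows)
  hid <- if ("hospital_id" %in% names(p_rows) && n > 0)
    p_rows$hospital_id[1] else NA_character_
  res <- list(hospital_id = hid, pairs = NULL, total_distance = NA_real_,
              eligible = TRUE, feasible = FALSE, non_converged = FALSE,
              fine_balance_satisfied = setNames(
                rep(NA, length(spec$fine_balance)), spec$fine_balance),
              binding_variable = NA_character_,
              near_exact_mismatches = setNames(
                rep(NA_integer_, length(spec$near_exact)), spec$near_exact),
              penalty = spec$penalty, template_data = t_rows,
              matched_data = NULL)
  class(res) <- "match_result"
  if (n < spec$ratio * m) {
    res$eligible <- FALSE
    return(res)
  }
  if (is.null(cov))
    cov <- cov(roster_design(rbind(t_rows, p_rows), spec$distance_roster))
  Xt <- roster_design(t_rows, spec$distance_roster)
  Xp <- roster_design(p_rows, spec$distance_roster)
  D <- mahal_cross_distance(Xt, Xp, cov)
  maxD <- max(D)
  pen <- spec$penalty %||% ((m + 1) * maxD)
  C <- D
  if (length(spec$near_exact) > 0)
    C <- C + pen * near_exact_mismatch_matrix(t_rows, p_rows,
                                              spec$near_exact)
  res$penalty <- pen

  sol <- solve_assignment_network(C, t_rows, p_rows, spec)
  if (sol$non_converged) {
    res$non_converged <- TRUE
    return(res)
  }
  pairs <- sol$pairs # template index -> pool row index
  res$pairs <- data.frame(template_index = seq_len(m),
                          pool_index = pairs)
  res$total_distance <- sum(D[cbind(seq_len(m), pairs)])
  res$matched_data <- p_rows[pairs, , drop = FALSE]
  for (v in spec$near_exact)
    res$near_exact_mismatches[[v]] <-
      sum(t_rows[[v]] != res$matched_data[[v]])
  ok <- TRUE
  for (v in spec$fine_balance) {
    chk <- fine_balance_check(t_rows, res$matched_data, v)
    res$fine_balance_satisfied[[v]] <- chk$satisfied
    if (!chk$satisfied && ok) {
      res$binding_variable <- v
      ok <- FALSE
    }
  }
  res$feasible <- ok
  res
}

# build and solve the min-cost-flow network for one hospital; returns
# pairs (length-m pool indices) or a non-convergence flag
solve_assignment_network <- function(C, t_rows, p_rows, spec) {
  m <- nrow(C); n <- ncol(C)
  fb <- spec$fine_balance
  L <- length(fb)
  # integer cost scaling with headroom for L penalty layers (see vignette)
  maxC <- max(C)
  unit <- min(1e9, 2^51 / max(1, as.double(m)^(L + 1)))
  S <- if (maxC > 0) unit / maxC else 1
  Ci <- round(C * S)
  B <- as.double(m) * unit + 1
  P <- numeric(L)
  if (L > 0) {
    P[L] <- B
    if (L > 1) for (l in (L - 1):1) P[l] <- m * P[l + 1] + B
  }

  lab_t <- fb_layer_labels(t_rows, fb)
  lab_p <- fb_layer_labels(p_rows, fb)

  q <- spec$sparse_neighbors
  repeat {
    if (!is.null(q) && q >= n) q <- NULL
    # arcs template -> pool (thinned to q nearest when requested)
    if (is.null(q)) {
      tp_from <- rep(seq_len(m), each = n)
      tp_to <- rep(seq_len(n), times = m)
      tp_cost <- as.vector(t(Ci))
    } else {
      nb <- t(apply(Ci, 1, function(r) order(r)[seq_len(q)]))
      tp_from <- rep(seq_len(m), each = q)
      tp_to <- as.vector(t(nb))
      tp_cost <- Ci[cbind(tp_from, tp_to)]
    }
    net <- build_fb_network(m, n, tp_from, tp_to, tp_cost,
                            lab_t, lab_p, P)
    if (net$n_nodes > spec$node_budget ||
        length(net$from) > spec$arc_budget)
      return(list(non_converged = TRUE))
    sol <- mcmf_solve(net$n_nodes, net$from, net$to, net$cap, net$cost,
                      net$source, net$sink, m)
    overflowed <- length(net$overflow_arcs) > 0 &&
      sum(sol$flow[net$overflow_arcs]) > 0
    if (sol$flow_sent == m && !(overflowed && !is.null(q))) {
      # accept: complete flow, and any fine-balance overflow occurred on
      # the dense network (i.e. balance is genuinely unattainable)
      f <- sol$flow[net$tp_arcs]
      sel <- which(f > 0.5)
      pairs <- integer(m)
      pairs[tp_from[sel]] <- tp_to[sel]
      return(list(non_converged = FALSE, pairs = pairs))
    }
    # thinned network infeasible: widen the neighborhood and retry
    if (is.null(q)) return(list(non_converged = TRUE)) # dense infeasible
    q <- min(n, 2 * q)
  }
}

# assemble the arc lists: source -> template -> pool -> fine-balance
# category layers (finest to coarsest, capacity = template count, plus an
# overflow arc with the layer penalty) -> sink
build_fb_network <- function(m, n, tp_from, tp_to, tp_cost,
                             lab_t, lab_p, P) {
  L <- length(P)
  source <- 0L
  t_node <- seq_len(m)            # 1..m
  p_node <- m + seq_len(n)        # m+1..m+n
  nxt <- m + n + 1L
  layer_nodes <- vector("list", L)
  layer_levels <- vector("list", L)
  for (l in seq_len(L)) {
    lev <- sort(unique(c(lab_t[[l]], lab_p[[l]])))
    layer_levels[[l]] <- lev
    layer_nodes[[l]] <- setNames(seq_along(lev) + nxt - 1L, lev)
    nxt <- nxt + length(lev)
  }
  sink <- nxt
  n_nodes <- nxt + 1L

  from <- c(rep(source, m), t_node[tp_from])
  to <- c(t_node, p_node[tp_to])
  cap <- c(rep(1, m), rep(1, length(tp_from)))
  cost <- c(rep(0, m), tp_cost)
  tp_arcs <- m + seq_along(tp_from)
  overflow_arcs <- integer(0)

  if (L == 0) {
    from <- c(from, p_node); to <- c(to, rep(sink, n))
    cap <- c(cap, rep(1, n)); cost <- c(cost, rep(0, n))
  } else {
    # pool row -> its finest-layer category
    from <- c(from, p_node)
    to <- c(to, unname(layer_nodes[[L]][lab_p[[L]]]))
    cap <- c(cap, rep(1, n)); cost <- c(cost, rep(0, n))
    for (l in L:1) {
      lev <- layer_levels[[l]]
      tcount <- table(factor(lab_t[[l]], levels = lev))
      if (l == 1) {
        parent <- rep(sink, length(lev))
      } else {
        par_lab <- vapply(strsplit(lev, "\r", fixed = TRUE),
                          function(s) paste(s[-length(s)], collapse = "\r"),
                          character(1))
        parent <- unname(layer_nodes[[l - 1]][par_lab])
      }
      nodes <- unname(layer_nodes[[l]])
      from <- c(from, nodes, nodes)
      to <- c(to, parent, parent)
      overflow_arcs <- c(overflow_arcs,
                         length(cap) + length(lev) + seq_along(lev))
      cap <- c(cap, as.numeric(tcount), rep(m, length(lev)))
      cost <- c(cost, rep(0, length(lev)), rep(P[l], length(lev)))
    }
  }
  list(n_nodes = n_nodes, from = as.integer(from), to = as.integer(to),
       cap = cap, cost = cost, source = source, sink = sink,
       tp_arcs = tp_arcs, overflow_arcs = overflow_arcs)
}

fine_balance_check <- function(t_rows, matched_rows, variable) {
  lev <- sort(unique(c(as.character(t_rows[[variable]]),
                       as.character(matched_rows[[variable]]))))
  tt <- table(factor(as.character(t_rows[[variable]]), levels = lev))
  mt <- table(factor(as.character(matched_rows[[variable]]), levels = lev))
  deficits <- as.integer(mt) - as.integer(tt)
  list(satisfied = all(deficits == 0L),
       deficits = data.frame(category = lev,
                             template = as.integer(tt),
                             matched = as.integer(mt),
                             deficit = deficits))
}

#' Check fine balance of a match result on one variable
#'
#' Recounts category totals from the matched rows, independently of the
#' solver: the flag is true iff every category count equals the template's
#' exactly.
#'
#' @param result A feasible-or-not `match_result` with matched rows.
#' @param variable Variable name.
#' @return List with `satisfied` flag and a per-category `deficits` table
#'   (matched minus template count).
#' @export
check_fine_balance <- function(result, variable) {
  if (is.null(result$matched_data))
    stop("match result carries no matched rows")
  if (!variable %in% names(result$template_data))
    stop("unknown variable: ", variable)
  fine_balance_check(result$template_data, result$matched_data, variable)
}

#' Match every hospital to the template
#'
#' @param template A `template`.
#' @param cohort Eligible `cohort_table`.
#' @param spec A [match_spec()].
#' @param hospital_ids Hospitals to match (default: all in `cohort`).
#' @return Named list of `match_result`, one per hospital.
#' @export
match_hospitals <- function(template, cohort, spec = match_spec(),
                            hospital_ids = NULL) {
  hospital_ids <- hospital_ids %||% sort(unique(cohort$hospital_id))
  cov <- pooled_covariance(cohort, spec$distance_roster)
  out <- lapply(hospital_ids, function(h) {
    optimal_match(template, cohort[cohort$hospital_id == h, , drop = FALSE],
                  spec, cov)
  })
  names(out) <- hospital_ids
  out
}

#' Serialize a match result (pair list CSV + diagnostics JSON)
#'
#' @param result A `match_result`.
#' @param csv_path,json_path Output paths.
#' @return `csv_path`, invisibly.
#' @export
write_match_result <- function(result, csv_path, json_path) {
  if (!is.null(result$pairs))
    write.csv(result$pairs, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(hospital_id = result$hospital_id,
         eligible = result$eligible, feasible = result$feasible,
         non_converged = result$non_converged,
         total_distance = result$total_distance,
         penalty = result$penalty,
         fine_balance_satisfied = as.list(result$fine_balance_satisfied),
         binding_variable = result$binding_variable,
         near_exact_mismatches = as.list(result$near_exact_mismatches)),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv_path)
}

#' @export
print.match_result <- function(x, ...) {
  status <- if (!x$eligible) "ineligible (pool below matching ratio)"
  else if (x$non_converged) "non-converged (network budget exceeded)"
  else if (x$feasible) sprintf("feasible, total distance %.3f",
                               x$total_distance)
  else sprintf("fine balance unattainable on '%s'", x$binding_variable)
  cat(sprintf("<match_result> hospital %s: %s\n", x$hospital_id, status))
  invisible(x)
}
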