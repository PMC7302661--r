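#' @name risk_model
#' @title Predicted 30-day mortality model
#'
#' @description
#' The illness-severity covariate used throughout the pipeline is the
#' predicted probability of 30-day mortality from a maximum-likelihood
#' logistic regression on admission characteristics: age, sex,
#' race/ethnicity, surgical indicator, admission-route indicators,
#' principal-diagnosis terms (the 7 broad categories plus indicators for
#' the most common fine categories), the 29 comorbidity indicators and the
#' 11 admission laboratory values. Model discrimination is summarised by
#' the c-statistic (area under the ROC curve).
NULL

#' Default covariate roster for the risk model
#'
#' `fine_top20` expands to indicators for the 20 most common fine
#' principal-diagnosis categories in the training cohort.
#'
#' @return Character vector of roster entries.
#' @export
default_risk_roster <- function() {
  c("age", "sex", "race_ethnicity", "dx_category", "fine_top20",
    "surgical", "ed_admission", "nursing_facility",
    paste0("cm_", comorbidity_names()), paste0("lab_", lab_names()))
}

# design matrix for the risk model; factors one-hot with reference level
# dropped, labs as z-scores, age centred at 65 per decade
risk_design <- function(cohort, roster, fine_levels = NULL) {
  n <- nrow(cohort)
  cols <- list()
  ctr <- lab_center(); scl <- lab_scale()
  for (v in roster) {
    if (v == "age") {
      cols[["age10"]] <- (cohort$age - 65) / 10
    } else if (v == "sex") {
      cols[["sexM"]] <- as.numeric(cohort$sex == "M")
    } else if (v == "race_ethnicity") {
      for (r in setdiff(race_levels(), "white"))
        cols[[paste0("race_", r)]] <- as.numeric(cohort$race_ethnicity == r)
    } else if (v == "dx_category") {
      for (d in setdiff(dx_categories(), "other"))
        cols[[paste0("dx_", d)]] <- as.numeric(cohort$dx_category == d)
    } else if (v == "fine_top20") {
      if (is.null(fine_levels)) {
        tab <- sort(table(cohort$fine_dx_category), decreasing = TRUE)
        fine_levels <- names(tab)[seq_len(min(20L, length(tab)))]
      }
      for (f in fine_levels)
        cols[[paste0("fine_", f)]] <-
          as.numeric(!is.na(cohort$fine_dx_category) &
                       cohort$fine_dx_category == f)
    } else if (startsWith(v, "lab_")) {
      ln <- sub("^lab_", "", v)
      cols[[paste0(v, "_z")]] <- (cohort[[v]] - ctr[[ln]]) / scl[[ln]]
    } else if (v %in% names(cohort)) {
      cols[[v]] <- as.numeric(cohort[[v]])
    } else {
      stop("roster column not found in cohort: ", v)
    }
  }
  X <- do.call(cbind, cols)
  list(X = X, fine_levels = fine_levels)
}

# penalized IRLS logistic fit (lambda = 0 gives plain ML)
irls_logistic <- function(X, y, lambda = 0, tol = 1e-8, maxit = 100) {
  X1 <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X1)
  beta <- numeric(p)
  beta[1] <- qlogis(max(min(mean(y), 1 - 1e-6), 1e-6))
  pen <- diag(c(0, rep(lambda, p - 1)))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X1, w * X1) + pen
    b <- crossprod(X1, w * z)
    new <- tryCatch(drop(solve(A, b)), error = function(e) NULL)
    if (is.null(new)) return(list(beta = beta, converged = FALSE,
                                  singular = TRUE, iter = it))
    if (max(abs(new - beta)) < tol) {
      beta <- new; converged <- TRUE; break
    }
    beta <- new
  }
  names(beta) <- colnames(X1)
  se <- tryCatch({
    eta <- drop(X1 %*% beta); mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    sqrt(diag(solve(crossprod(X1, w * X1) + pen)))
  }, error = function(e) rep(NA_real_, p))
  names(se) <- colnames(X1)
  list(beta = beta, se = se, converged = converged, singular = FALSE,
       iter = it)
}

#' Fit the predicted 30-day mortality model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, tolerance 1e-8, at most 100 iterations). Rows with a missing
#' principal diagnosis are excluded from fitting and receive `NA`
#' predictions (they are removed by the eligibility cascade anyway).
#' Apparent separation (non-convergence or exploding coefficients) triggers
#' a weak-ridge refit with a warning flag in the returned model.
#'
#' @param cohort A `cohort_table` containing `died_30d`.
#' @param roster Covariate roster, see [default_risk_roster()].
#' @return A `risk_model` object: coefficients, training c-statistic,
#'   roster, flags; the input cohort with `predicted_mortality` filled is
#'   in `$cohort`.
#' @export
fit_risk_model <- function(cohort, roster = default_risk_roster()) {
  stopifnot(inherits(cohort, "cohort_table"))
  use <- !is.na(cohort$dx_category)
  y <- cohort$died_30d[use]
  if (length(unique(y)) < 2)
    stop("outcome has a single class; cannot fit risk model")
  des <- risk_design(cohort[use, , drop = FALSE], roster)
  fit <- irls_logistic(des$X, y)
  ridge <- FALSE
  if (!fit$converged || fit$singular || any(abs(fit$beta) > 15)) {
    fit <- irls_logistic(des$X, y, lambda = 1e-4)
    ridge <- TRUE
    warning("risk model showed separation or non-convergence; ",
            "refit with a weak ridge penalty")
  }
  eta <- drop(cbind(1, des$X) %*% fit$beta)
  pred <- rep(NA_real_, nrow(cohort))
  pred[use] <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
  cohort$predicted_mortality <- pred
  cs <- c_statistic(pred[use], y)
  structure(list(coefficients = fit$beta[-1],
                 intercept = fit$beta[[1]],
                 se = fit$se,
                 c_statistic = cs,
                 roster = roster,
                 fine_levels = des$fine_levels,
                 ridge = ridge,
                 converged = fit$converged,
                 cohort = cohort),
            class = "risk_model")
}

#' Predict 30-day mortality for new hospitalizations
#'
#' @param object A `risk_model`.
#' @param newdata A `cohort_table`.
#' @param ... Unused.
#' @return Vector of predicted probabilities (`NA` for rows with missing
#'   principal diagnosis).
#' @export
predict.risk_model <- function(object, newdata, ...) {
  use <- !is.na(newdata$dx_category)
  des <- risk_design(newdata[use, , drop = FALSE], object$roster,
                     fine_levels = object$fine_levels)
  eta <- object$intercept + drop(des$X %*% object$coefficients)
  out <- rep(NA_real_, nrow(newdata))
  out[use] <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
  out
}

#' Concordance statistic (area under the ROC curve)
#'
#' Probability that a randomly chosen death is assigned a higher predicted
#' risk than a randomly chosen survivor, ties counted one half; equal to
#' the normalized Mann-Whitney statistic, computed from mid-ranks.
#'
#' @param predictions Numeric risk scores.
#' @param outcomes Binary 0/1 outcomes of the same length.
#' @return Value in \[0, 1\].
#' @export
c_statistic <- function(predictions, outcomes) {
  if (length(predictions) != length(outcomes))
    stop("predictions and outcomes differ in length")
  ok <- !is.na(predictions) & !is.na(outcomes)
  predictions <- predictions[ok]; outcomes <- outcomes[ok]
  n1 <- sum(outcomes == 1); n0 <- sum(outcomes == 0)
  if (n1 == 0 || n0 == 0)
    stop("c-statistic undefined: one outcome class absent")
  r <- rank(predictions) # mid-ranks handle ties as 1/2
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Serialize a risk model to JSON
#'
#' @param model A `risk_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_risk_model <- function(model, path) {
  jsonlite::write_json(
    list(intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         c_statistic = model$c_statistic,
         roster = model$roster,
         fine_levels = model$fine_levels,
         ridge = model$ridge),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %d coefficients; c-statistic %.3f%s\n",
              length(x$coefficients), x$c_statistic,
              if (x$ridge) " (ridge fallback)" else ""))
  invisible(x)
}
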