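#' @name pipeline_io
#' @title Configuration and end-to-end pipeline
#'
#' @description
#' Runs the full benchmarking study from one configuration: generate (or
#' load) the cohort, fit the risk model, apply the eligibility cascade,
#' select the template (or one per tier), run each configured matching
#' run, audit match quality, rank hospitals by template matching and by
#' the regression comparator, and compare category assignments. Every
#' artifact is written to the output directory together with a
#' machine-readable manifest (config hash, seed, artifact checksums) so
#' identical config + seed reproduces identical manifests.
NULL

#' Build a pipeline run configuration
#'
#' @param input Path to a cohort CSV, or `NULL` to generate synthetically.
#' @param generator [system_config()] used when `input` is `NULL`.
#' @param template_size Template size m.
#' @param candidates Number of candidate templates k.
#' @param mode `"single_template"` or `"tiered"`.
#' @param match_specs Named list of [match_spec()] (the matching runs).
#' @param risk_roster Risk-model covariate roster.
#' @param selection_roster Template-selection roster.
#' @param balance_p,crossmatch_p,psych_share Thresholds in (0, 1).
#' @param ratio Matching-ratio requirement.
#' @param rare_per Rare-diagnosis denominator.
#' @param seed Integer master seed.
#' @param output_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, generator = system_config(),
                       template_size = 300, candidates = 1000,
                       mode = c("single_template", "tiered"),
                       match_specs = list(primary = match_spec()),
                       risk_roster = default_risk_roster(),
                       selection_roster = default_selection_roster(),
                       balance_p = 0.05, crossmatch_p = 0.05,
                       psych_share = 0.90, ratio = 3L, rare_per = 300,
                       seed = 1L, output_dir = tempfile("tmbench_run_")) {
  mode <- match.arg(mode)
  if (template_size < 1 || candidates < 1)
    stop("template_size and candidates must be >= 1")
  for (th in c(balance_p, crossmatch_p, psych_share))
    if (th <= 0 || th >= 1) stop("thresholds must lie in (0, 1)")
  stopifnot(is.list(match_specs), length(match_specs) >= 1)
  structure(list(input = input, generator = generator,
                 template_size = template_size, candidates = candidates,
                 mode = mode, match_specs = match_specs,
                 risk_roster = risk_roster,
                 selection_roster = selection_roster,
                 balance_p = balance_p, crossmatch_p = crossmatch_p,
                 psych_share = psych_share, ratio = as.integer(ratio),
                 rare_per = rare_per, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Scalar fields override the [run_config()] defaults; `generator` and
#' `match_specs` entries are passed to [system_config()] and
#' [match_spec()].
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- raw
  if (!is.null(raw$generator))
    args$generator <- do.call(system_config, raw$generator)
  if (!is.null(raw$match_specs))
    args$match_specs <- lapply(raw$match_specs,
                               function(s) do.call(match_spec, s))
  do.call(run_config, args)
}

stage_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full benchmarking pipeline
#'
#' Stages: generate/load -> risk model -> eligibility cascade -> template
#' selection -> matching run(s) -> cross-match and balance diagnostics ->
#' matched-sample ranking and regression comparator -> category
#' comparisons -> manifest. A failure in any stage halts the pipeline with
#' a stage-tagged error; artifacts written before the failure are
#' retained.
#'
#' @param config A [run_config()].
#' @param verbose Log per-stage progress (default TRUE).
#' @return Invisibly, a list with all in-memory artifacts (cohort, risk
#'   model, exclusion log, templates, match results, diagnostics, reports,
#'   comparisons, manifest).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "init"
  artifacts <- list()
  on_fail <- function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    stage <- "cohort"
    truth <- NULL
    if (is.null(config$input)) {
      gen <- generate_system(config$generator, seed = config$seed)
      cohort <- gen$cohort
      truth <- gen$truth
      write_profiles(gen$profiles, file.path(out_dir, "profiles.json"))
      write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    } else {
      cohort <- load_cohort(config$input)
    }
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    stage_log(verbose, stage, "%d rows at %d hospitals", nrow(cohort),
              length(unique(cohort$hospital_id)))

    stage <- "risk_model"
    rm_fit <- fit_risk_model(cohort, config$risk_roster)
    cohort <- rm_fit$cohort
    write_risk_model(rm_fit, file.path(out_dir, "risk_model.json"))
    stage_log(verbose, stage, "c-statistic %.3f", rm_fit$c_statistic)

    stage <- "exclusions"
    ex <- apply_exclusions(cohort, config$template_size, config$ratio,
                           config$psych_share, config$rare_per)
    eligible <- ex$cohort
    write_exclusion_log(ex$log, file.path(out_dir, "exclusions.json"))
    stage_log(verbose, stage, "%d eligible rows at %d hospitals",
              nrow(eligible), length(unique(eligible$hospital_id)))

    stage <- "template"
    if (config$mode == "single_template") {
      cand <- draw_candidates(eligible, config$template_size,
                              config$candidates, seed = config$seed)
      templates <- list(all = select_template(eligible, cand,
                                              config$selection_roster))
    } else {
      templates <- select_tier_templates(
        eligible, config$template_size, config$candidates,
        seed = config$seed, roster = config$selection_roster,
        ratio = config$ratio)
    }
    for (nm in names(templates))
      write_template(templates[[nm]],
                     file.path(out_dir, sprintf("template_%s.csv", nm)),
                     file.path(out_dir, sprintf("template_%s.json", nm)))
    stage_log(verbose, stage, "%d template(s); distance(s) %s",
              length(templates),
              paste(sprintf("%.4f", vapply(templates, `[[`, 1,
                                           "distance")), collapse = ", "))

    stage <- "matching"
    runs <- list()
    for (rn in names(config$match_specs)) {
      spec <- config$match_specs[[rn]]
      results <- list()
      for (nm in names(templates)) {
        tmpl <- templates[[nm]]
        pool <- if (config$mode == "tiered")
          eligible[eligible$tier == tmpl$tier, , drop = FALSE]
        else eligible
        results <- c(results, match_hospitals(tmpl, pool, spec))
      }
      runs[[rn]] <- results
      ok <- vapply(results, function(r)
        isTRUE(r$feasible), logical(1))
      stage_log(verbose, stage, "run '%s': %d/%d hospitals feasible",
                rn, sum(ok), length(results))
      for (h in names(results))
        write_match_result(
          results[[h]],
          file.path(out_dir, sprintf("match_%s_%s.csv", rn, h)),
          file.path(out_dir, sprintf("match_%s_%s.json", rn, h)))
    }

    stage <- "diagnostics"
    diag <- list()
    for (rn in names(runs)) {
      spec <- config$match_specs[[rn]]
      results <- Filter(function(r) !is.null(r$matched_data), runs[[rn]])
      cm <- lapply(results, function(r)
        crossmatch_test(r$template_data, r$matched_data,
                        roster = spec$distance_roster,
                        threshold = config$crossmatch_p))
      cm_df <- data.frame(
        hospital_id = names(results),
        a1 = vapply(cm, `[[`, 1, "a1"),
        p_value = vapply(cm, `[[`, 1, "p_value"),
        poorly_matched = vapply(cm, `[[`, TRUE, "poorly_matched"))
      bal <- balance_table(lapply(results, `[[`, "matched_data"),
                           roster = spec$distance_roster,
                           threshold = config$balance_p)
      diag[[rn]] <- list(crossmatch = cm_df, balance = bal)
      write.csv(cm_df, file.path(out_dir, sprintf("crossmatch_%s.csv", rn)),
                row.names = FALSE)
      write.csv(as.data.frame(bal),
                file.path(out_dir, sprintf("balance_%s.csv", rn)),
                row.names = FALSE)
      stage_log(verbose, stage,
                "run '%s': %d poorly matched; %d/%d variables balanced",
                rn, sum(cm_df$poorly_matched), attr(bal, "n_balanced"),
                nrow(bal))
    }

    stage <- "benchmarking"
    reports <- list()
    for (rn in names(runs)) {
      rep <- rank_matched(runs[[rn]])
      if (nrow(rep) >= 5) rep <- categorize(rep)
      reports[[rn]] <- rep
      write.csv(as.data.frame(rep),
                file.path(out_dir, sprintf("benchmark_matched_%s.csv", rn)),
                row.names = FALSE)
    }
    reg <- rank_regression(eligible)
    if (nrow(reg) >= 5) reg <- categorize(reg)
    write.csv(as.data.frame(reg),
              file.path(out_dir, "benchmark_regression.csv"),
              row.names = FALSE)

    stage <- "comparison"
    comparisons <- list()
    pairs <- c(lapply(names(reports), function(rn)
      list(a = rn, b = "regression", ra = reports[[rn]], rb = reg)))
    if (length(reports) > 1) {
      nm <- names(reports)
      for (i in seq_along(nm)[-1])
        pairs <- c(pairs, list(list(a = nm[1], b = nm[i],
                                    ra = reports[[nm[1]]],
                                    rb = reports[[nm[i]]])))
    }
    for (p in pairs) {
      if (is.null(p$ra$category) || is.null(p$rb$category)) next
      cmp <- compare_rankings(p$ra, p$rb)
      comparisons[[paste(p$a, "vs", p$b)]] <- cmp
    }
    jsonlite::write_json(
      lapply(comparisons, function(cmp)
        list(table = as.data.frame(cmp$table), statistic = cmp$statistic,
             df = cmp$df, p_value = cmp$p_value,
             agreement = cmp$agreement)),
      file.path(out_dir, "comparisons.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)

    stage <- "manifest"
    manifest <- build_manifest(config, out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    artifacts <- list(cohort = cohort, truth = truth, risk_model = rm_fit,
                      exclusion_log = ex$log, eligible = eligible,
                      templates = templates, matches = runs,
                      diagnostics = diag, reports = reports,
                      regression = reg, comparisons = comparisons,
                      manifest = manifest, output_dir = out_dir)
    invisible(artifacts)
  }, error = on_fail)
}

# manifest with config hash and checksums of every artifact file;
# deliberately free of timestamps and of the output location, so
# identical config + seed reproduces an identical manifest anywhere
build_manifest <- function(config, out_dir) {
  hashed <- unclass_deep(config)
  hashed$output_dir <- NULL
  cfg_json <- jsonlite::toJSON(hashed, auto_unbox = TRUE,
                               digits = NA, null = "null")
  cfg_file <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  sums <- tools::md5sum(file.path(out_dir, files))
  list(package_version = as.character(utils::packageVersion("templatebench")),
       seed = config$seed,
       config_md5 = unname(tools::md5sum(cfg_file)),
       artifacts = as.list(setNames(unname(sums), files)))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
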