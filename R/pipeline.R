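#' Configuration for the full uplift workflow
#'
#' Encodes the study flow: outer registration-order split into training and
#' test halves, inner split of the training half into a model-training part
#' and a Qini-validation part, preprocessing thresholds, the candidate
#' classifier list and a single seed from which all stage randomness is
#' derived.
#'
#' @param cohort A `cohort_table`, or `NULL` to generate one from
#'   `synthetic`.
#' @param synthetic A [synthetic_config()] (used when `cohort` is `NULL`).
#' @param outer_sizes,inner_sizes Integer pairs for the two
#'   registration-order splits; `NULL` uses `(ceiling(n/2), floor(n/2))`.
#' @param missing_threshold,r_threshold Preprocessing thresholds (defaults
#'   0.15 and 0.7).
#' @param classifiers Candidate registry ids (default: the mandatory set).
#' @param keep_priority Ordered feature names resolving correlated groups.
#' @param seed Integer master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, synthetic = NULL,
                            outer_sizes = NULL, inner_sizes = NULL,
                            missing_threshold = 0.15, r_threshold = 0.7,
                            classifiers = mandatory_classifiers(),
                            keep_priority = NULL, seed = 1L) {
  if (is.null(cohort) && is.null(synthetic))
    stop("supply a cohort or a synthetic config", call. = FALSE)
  if (length(classifiers) == 0)
    stop("classifier list must be non-empty", call. = FALSE)
  stopifnot(missing_threshold >= 0, missing_threshold <= 1,
            r_threshold >= 0, r_threshold <= 1)
  structure(list(cohort = cohort, synthetic = synthetic,
                 outer_sizes = outer_sizes, inner_sizes = inner_sizes,
                 missing_threshold = missing_threshold,
                 r_threshold = r_threshold,
                 classifiers = classifiers,
                 keep_priority = keep_priority,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Preset reproducing the trial's workflow shape on synthetic data
#'
#' A 497-subject synthetic cohort split 249/248 by registration order, the
#' training half split again 124/125 (the first part trains the models, the
#' second computes Qini coefficients), preprocessing thresholds 0.15 and
#' 0.7, and all mandatory classifiers as candidates.
#'
#' @param seed Integer master seed.
#' @param ... Further arguments passed to [synthetic_config()].
#' @return A `pipeline_config`.
#' @export
paper_shape_config <- function(seed = 1L, ...) {
  pipeline_config(
    synthetic = synthetic_config(n = 497, seed = derive_seed(seed, 1), ...),
    outer_sizes = c(249, 248), inner_sizes = c(124, 125),
    missing_threshold = 0.15, r_threshold = 0.7,
    classifiers = mandatory_classifiers(), seed = seed)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full uplift workflow
#'
#' Split (outer) -> split (inner) -> fit preprocessing recipe on the
#' model-training part -> fit every candidate classifier -> Qini evaluation
#' on the validation part -> select the highest-Qini model and freeze its
#' optimal cutoff -> score the untouched test half -> stratify at the cutoff
#' -> per-stratum survival comparison, treatment-by-stratum interaction and
#' characteristics tables. Test data are never read before model and cutoff
#' are frozen. A test stratum with no subjects, or with an arm or event
#' missing, yields a degenerate-stratum warning in the report instead of a
#' failure.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  cohort <- stage("cohort", {
    if (!is.null(config$cohort)) config$cohort
    else generate_cohort(config$synthetic)$cohort
  })

  outer <- stage("outer_split",
                 split_by_registration_order(cohort, config$outer_sizes))
  inner <- stage("inner_split",
                 split_by_registration_order(outer$first, config$inner_sizes))
  train <- inner$first
  validation <- inner$second
  test <- outer$second

  recipe <- stage("preprocess", fit_preprocess_recipe(
    train, config$missing_threshold, config$r_threshold,
    config$keep_priority))

  summaries <- list()
  models <- list()
  for (i in seq_along(config$classifiers)) {
    id <- config$classifiers[i]
    stage(paste0("fit_", id), {
      model <- fit_uplift_model(train, id, recipe,
                                seed = derive_seed(seed, 100 + i))
      val_scores <- uplift_scores(model, validation)
      models[[id]] <- model
      summaries[[id]] <- qini_summary(val_scores$uplift_score,
                                      validation$data$arm,
                                      validation$data$success,
                                      classifier_id = id)
    })
  }

  selected_id <- stage("model_selection", select_best_model(summaries))
  cutoff <- summaries[[selected_id]]$optimal_cutoff
  warnings <- character(0)
  if (isTRUE(attr(cutoff, "no_benefit")))
    warnings <- c(warnings,
                  "selected model shows no positive Qini separation; cutoff set to +Inf (no-benefit)")

  test_scores <- stage("score_test",
                       uplift_scores(models[[selected_id]], test))
  strata <- stratify_by_cutoff(test_scores$uplift_score, as.numeric(cutoff))

  comparisons <- list()
  tables <- list()
  interaction <- NULL
  td <- test$data
  for (s in c("high", "low")) {
    sel <- strata == s
    if (!any(sel)) {
      warnings <- c(warnings, paste0("degenerate stratum: '", s,
                                     "' contains no test subjects"))
      next
    }
    ok <- any(td$arm[sel] == "treatment") && any(td$arm[sel] == "control") &&
      sum(td$event_indicator[sel]) >= 1
    if (!ok) {
      warnings <- c(warnings, paste0("degenerate stratum: '", s,
                                     "' lacks an arm or has no events"))
      next
    }
    comparisons[[s]] <- stratum_comparison(td$event_time[sel],
                                           td$event_indicator[sel],
                                           td$arm[sel], stratum = s)
    tables[[paste0("arm_within_", s)]] <-
      characteristics_table(
        cohort_table(td[sel, , drop = FALSE], test$schema, test$horizon),
        td$arm[sel])
  }
  tables$test_by_stratum <- characteristics_table(test, strata)

  cell_tab <- table(td$arm, strata)
  if (all(dim(cell_tab) == c(2, 2)) && all(cell_tab > 0)) {
    interaction <- stage("interaction", cox_interaction(
      td$event_time, td$event_indicator, td$arm, as.character(strata)))
  } else {
    warnings <- c(warnings,
                  "interaction model skipped: empty arm-by-stratum cell")
  }

  structure(list(
    qini_summaries = summaries,
    model_selection = data.frame(
      classifier_id = names(summaries),
      qini_coefficient = vapply(summaries, `[[`, numeric(1),
                                "qini_coefficient"),
      optimal_cutoff = vapply(summaries, function(s)
        as.numeric(s$optimal_cutoff), numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE),
    selected_classifier = selected_id,
    selected_model = models[[selected_id]],
    cutoff = cutoff,
    test_scores = test_scores,
    strata = strata,
    stratum_sizes = c(high = sum(strata == "high"),
                      low = sum(strata == "low")),
    comparisons = comparisons,
    interaction = interaction,
    tables = tables,
    warnings = warnings,
    provenance = list(seed = seed,
                      config_hash = rlang::hash(unclass(config)),
                      n = n_subjects(cohort),
                      package_version = as.character(
                        utils::packageVersion("upliftRCT")))),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat("  selected:", x$selected_classifier,
      sprintf("(Qini %.4f)\n",
              x$model_selection$qini_coefficient[
                x$model_selection$classifier_id == x$selected_classifier]))
  cat(sprintf("  cutoff: %s | test strata high/low: %d/%d\n",
              format(as.numeric(x$cutoff), digits = 4),
              x$stratum_sizes[["high"]], x$stratum_sizes[["low"]]))
  for (s in names(x$comparisons)) print(x$comparisons[[s]])
  if (!is.null(x$interaction))
    cat(sprintf("  interaction P = %.3f\n", x$interaction$interaction_p))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Export a pipeline report to a directory
#'
#' Writes the model-selection table, per-candidate Qini curves, the selected
#' cutoff, stratified survival outcomes (counts, HR, CI, p-values,
#' interaction p) as JSON, the characteristics tables, Kaplan-Meier step
#' functions and a human-readable summary. Re-exporting the same report
#' produces identical file contents.
#'
#' @param report A `pipeline_report`.
#' @param directory Output directory (created if needed).
#' @param plot Also write a Qini-curve PNG? Default `FALSE`.
#' @return Character vector of written paths, invisibly.
#' @export
export_report <- function(report, directory, plot = FALSE) {
  stopifnot(inherits(report, "pipeline_report"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok || file.access(directory, mode = 2) != 0)
    stop("directory not writable: ", directory, call. = FALSE)
  paths <- character(0)
  wr <- function(rel) {
    p <- file.path(directory, rel)
    paths <<- c(paths, p)
    p
  }

  utils::write.csv(report$model_selection, wr("model_selection.csv"),
                   row.names = FALSE)
  for (id in names(report$qini_summaries))
    write_qini_curve(report$qini_summaries[[id]]$points,
                     wr(paste0("qini_curve_", id, ".csv")))

  outcomes <- list(
    selected_classifier = report$selected_classifier,
    cutoff = as.numeric(report$cutoff),
    no_benefit = isTRUE(attr(report$cutoff, "no_benefit")),
    stratum_sizes = as.list(report$stratum_sizes),
    strata = lapply(report$comparisons, function(cmp) list(
      per_arm = cmp$per_arm,
      hazard_ratio = cmp$hazard_ratio,
      ci95 = cmp$ci95, cox_p = cmp$cox_p, logrank_p = cmp$logrank_p)),
    interaction_p = if (is.null(report$interaction)) NULL
                    else report$interaction$interaction_p,
    warnings = report$warnings,
    provenance = report$provenance)
  jsonlite::write_json(outcomes, wr("stratified_outcomes.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  for (nm in names(report$tables))
    utils::write.csv(report$tables[[nm]],
                     wr(paste0("characteristics_", nm, ".csv")),
                     row.names = FALSE)
  for (s in names(report$comparisons))
    for (a in c("control", "treatment"))
      utils::write.csv(
        as.data.frame(report$comparisons[[s]]$km_curves[[a]]),
        wr(paste0("km_", s, "_", a, ".csv")), row.names = FALSE)

  forest <- do.call(rbind, lapply(report$comparisons, function(cmp)
    data.frame(stratum = cmp$stratum, hazard_ratio = cmp$hazard_ratio,
               ci_low = cmp$ci95[1], ci_high = cmp$ci95[2],
               cox_p = cmp$cox_p, stringsAsFactors = FALSE)))
  if (!is.null(forest))
    utils::write.csv(forest, wr("forest_plot.csv"), row.names = FALSE)

  if (plot) {
    grDevices::png(wr("qini_curves.png"), width = 800, height = 600)
    plot_qini_curves(report$qini_summaries)
    grDevices::dev.off()
  }

  con <- file(wr("summary.txt"), "w")
  sink(con)
  print(report)
  sink()
  close(con)
  invisible(paths)
}
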