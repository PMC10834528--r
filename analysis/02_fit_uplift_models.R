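#!/usr/bin/env Rscript
# Step 2: class-variable transformation, candidate fitting and Qini model
# selection.
#
# Splits the simulated cohort 249/248 by registration order, the training
# half again 124/125, fits the preprocessing recipe and every mandatory
# classifier on the 124-subject part, and ranks candidates by Qini
# coefficient on the 125-subject validation part.

suppressMessages(library(upliftRCT))
seed <- as.integer(Sys.getenv("UPLIFT_SEED", "1"))
dir.create("results", showWarnings = FALSE)

cohort <- load_cohort("results/synthetic_cohort.csv")
outer <- split_by_registration_order(cohort, c(249, 248))
inner <- split_by_registration_order(outer$first, c(124, 125))
cat(sprintf("splits: train %d / validation %d / test %d\n",
            n_subjects(inner$first), n_subjects(inner$second),
            n_subjects(outer$second)))

recipe <- fit_preprocess_recipe(inner$first, missing_threshold = 0.15,
                                r_threshold = 0.7)
print(recipe)
write_recipe(recipe, "results/preprocess_recipe.json")

summaries <- list()
for (id in mandatory_classifiers()) {
  model <- fit_uplift_model(inner$first, id, recipe, seed = seed)
  sc <- uplift_scores(model, inner$second)
  summaries[[id]] <- qini_summary(sc$uplift_score, inner$second$data$arm,
                                  inner$second$data$success, id)
  write_qini_curve(summaries[[id]]$points,
                   paste0("results/qini_curve_", id, ".csv"))
}

selection <- data.frame(
  classifier_id = names(summaries),
  qini_coefficient = sapply(summaries, `[[`, "qini_coefficient"),
  optimal_cutoff = sapply(summaries, function(s) as.numeric(s$optimal_cutoff)),
  row.names = NULL)
selection <- selection[order(-selection$qini_coefficient), ]
write.csv(selection, "results/model_selection.csv", row.names = FALSE)

best <- select_best_model(summaries)
cat("\nmodel selection (validation Qini coefficients):\n")
print(selection, row.names = FALSE)
cat(sprintf("\nselected: %s with cutoff %.4f\n", best,
            as.numeric(summaries[[best]]$optimal_cutoff)))

sel_model <- fit_uplift_model(inner$first, best, recipe, seed = seed)
if (available_classifiers()$supports_importance[
      available_classifiers()$id == best]) {
  imp <- gini_importance(sel_model)
  write.csv(imp, "results/gini_importance.csv", row.names = FALSE)
  cat("\ntop features by Gini importance:\n")
  print(head(imp, 10), row.names = FALSE)
}
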