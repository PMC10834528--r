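#' Class-variable transformation
#'
#' Relabels each subject with `z = 1` for treated successes and control
#' failures, `z = 0` otherwise. With 1:1 randomization, a classifier's
#' `P(z = 1 | x)` then carries the individual treatment effect through the
#' identity `P_T(Y=1|x) - P_C(Y=1|x) = 2 P(z=1|x) - 1`, turning uplift
#' estimation into a single binary classification.
#'
#' @param arm Character/factor vector of `"treatment"`/`"control"`.
#' @param success Binary 0/1 vector.
#' @return Integer 0/1 vector `z`.
#' @export
transform_class_variable <- function(arm, success) {
  stopifnot(length(arm) == length(success),
            all(arm %in% c("treatment", "control")),
            all(success %in% c(0, 1)))
  as.integer((arm == "treatment") == (success == 1))
}

# one-hot design matrix with reference-level contrasts; factor levels are
# frozen at fit time so prediction reproduces the training columns
build_design <- function(cohort, xlevels = NULL) {
  feats <- covariate_data(cohort)
  schema <- cohort$schema
  levs <- list()
  for (f in names(schema)) {
    if (schema[[f]] == "categorical") {
      v <- as.character(feats[[f]])
      lev <- if (is.null(xlevels)) sort(unique(v)) else xlevels[[f]]
      unseen <- !(v %in% lev)
      if (any(unseen)) {
        if ("not available" %in% lev) v[unseen] <- "not available"
        else stop("schema mismatch: unseen level(s) in feature '", f, "'",
                  call. = FALSE)
      }
      levs[[f]] <- lev
      # a single-level factor carries no information; keep a constant
      # column so the design is stable across fit and predict
      feats[[f]] <- if (length(lev) < 2) rep(0, length(v))
                    else factor(v, levels = lev)
    }
  }
  mm <- stats::model.matrix(~ ., data = feats)
  assign_idx <- attr(mm, "assign")
  mm <- mm[, -1, drop = FALSE]
  feature_map <- stats::setNames(names(feats)[assign_idx[-1]], colnames(mm))
  colnames(mm) <- make.names(colnames(mm), unique = TRUE)
  names(feature_map) <- colnames(mm)
  list(x = mm, xlevels = levs, feature_map = feature_map)
}

#' Fit a one-model uplift classifier
#'
#' Applies the training-fitted preprocessing recipe, computes the
#' transformed class variable `z`, one-hot encodes categoricals (the
#' imputation level `"not available"` is an ordinary level) and fits the
#' requested registry classifier to predict `P(z = 1 | x)`. Deterministic
#' given `seed`.
#'
#' @param train Training `cohort_table` containing both arms.
#' @param classifier_id Registry id, see [available_classifiers()].
#' @param recipe A `preprocess_recipe` fitted on the same training cohort.
#' @param seed Integer seed for any classifier randomness.
#' @param hyperparameters Named list overriding the registry defaults.
#' @return An `uplift_model`.
#' @export
fit_uplift_model <- function(train, classifier_id, recipe, seed = 1L,
                             hyperparameters = list()) {
  stopifnot(inherits(train, "cohort_table"))
  spec <- get_classifier(classifier_id)
  if (!any(train$data$arm == "treatment") ||
      !any(train$data$arm == "control"))
    stop("training cohort must contain both arms", call. = FALSE)
  processed <- apply_recipe(recipe, train)
  z <- transform_class_variable(processed$data$arm, processed$data$success)
  if (length(unique(z)) < 2)
    stop("degenerate fit: transformed class variable has a single class",
         call. = FALSE)
  design <- build_design(processed)
  hp <- utils::modifyList(spec$hyperparameters, hyperparameters)
  set.seed(seed)
  fitted <- spec$fit(design$x, z, hp)
  structure(list(classifier_id = classifier_id,
                 fitted = fitted,
                 recipe = recipe,
                 xlevels = design$xlevels,
                 columns = colnames(design$x),
                 feature_map = design$feature_map,
                 hyperparameters = hp,
                 seed = as.integer(seed),
                 training_fingerprint = rlang::hash(
                   list(classifier_id, design$x, z, seed, hp))),
            class = "uplift_model")
}

#' @export
print.uplift_model <- function(x, ...) {
  cat("uplift_model:", x$classifier_id, "on", length(x$columns),
      "design columns (", length(x$recipe$kept_features), "features )\n")
  invisible(x)
}

#' Uplift scores for a cohort
#'
#' `score_i = 2 p_i - 1` where `p_i` is the model's predicted
#' `P(z = 1 | x_i)`; bounded in [-1, 1]. Positive scores flag subjects whose
#' success probability is predicted higher under treatment than control.
#' Classifier calibration is not enforced: a poorly calibrated classifier
#' distorts the score scale but not the ranking the Qini analysis uses.
#'
#' @param model An `uplift_model`.
#' @param cohort A `cohort_table` conforming to the model's recipe schema.
#' @return data.frame `(subject_id, probability, uplift_score)` in cohort
#'   order.
#' @export
uplift_scores <- function(model, cohort) {
  stopifnot(inherits(model, "uplift_model"), inherits(cohort, "cohort_table"))
  processed <- apply_recipe(model$recipe, cohort)
  design <- build_design(processed, xlevels = model$xlevels)
  if (!identical(colnames(design$x), model$columns))
    stop("schema mismatch: design columns differ from the fitted model",
         call. = FALSE)
  spec <- get_classifier(model$classifier_id)
  p <- spec$predict_prob(model$fitted, design$x)
  data.frame(subject_id = processed$data$subject_id,
             probability = p,
             uplift_score = 2 * p - 1,
             stringsAsFactors = FALSE)
}

#' Gini (impurity-decrease) feature importance of a fitted uplift model
#'
#' Raw importances over one-hot design columns are aggregated back to their
#' source features (a categorical feature's dummies sum into one entry),
#' normalized to sum to 1 and ranked.
#'
#' @param model An `uplift_model` whose classifier supports impurity-based
#'   importance (tree ensembles).
#' @return data.frame `(feature, importance)` in descending order.
#' @export
gini_importance <- function(model) {
  stopifnot(inherits(model, "uplift_model"))
  spec <- get_classifier(model$classifier_id)
  if (!spec$supports_importance)
    stop("classifier '", model$classifier_id,
         "' does not support impurity-based importance", call. = FALSE)
  raw <- spec$importance(model$fitted)
  raw <- raw[raw > 0 & names(raw) %in% names(model$feature_map)]
  if (length(raw) == 0 || sum(raw) <= 0)
    stop("no importance available (model has no splits)", call. = FALSE)
  src <- model$feature_map[names(raw)]
  agg <- tapply(as.numeric(raw), src, sum)
  agg <- agg / sum(agg)
  out <- data.frame(feature = names(agg), importance = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  out
}
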