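# Registry of probabilistic classifiers behind the fit/predict-probability
# contract. Each entry provides fit(x, z, hyperparameters) and
# predict_prob(fitted, x); tree ensembles additionally expose an
# impurity-based importance over design-matrix columns.

.classifiers <- new.env(parent = emptyenv())

#' Register a probabilistic classifier
#'
#' @param id Unique registry id.
#' @param label Human-readable family name.
#' @param fit Function `(x, z, hyperparameters)` returning a fitted object;
#'   `x` is the one-hot numeric design matrix, `z` the binary 0/1 target.
#'   Any randomness must respect the RNG state (the caller seeds it).
#' @param predict_prob Function `(fitted, x)` returning `P(z = 1 | x)`.
#' @param supports_importance Whether impurity-based (Gini) importance is
#'   available.
#' @param importance Function `(fitted)` returning a named non-negative
#'   vector over design columns; required when `supports_importance`.
#' @param hyperparameters Named list of defaults, fully exposed to callers.
#' @return The id, invisibly.
#' @export
register_classifier <- function(id, label, fit, predict_prob,
                                supports_importance = FALSE,
                                importance = NULL,
                                hyperparameters = list()) {
  if (exists(id, envir = .classifiers, inherits = FALSE))
    stop("classifier id '", id, "' is already registered", call. = FALSE)
  if (supports_importance && is.null(importance))
    stop("importance function required when supports_importance", call. = FALSE)
  assign(id, list(id = id, label = label, fit = fit,
                  predict_prob = predict_prob,
                  supports_importance = supports_importance,
                  importance = importance,
                  hyperparameters = hyperparameters,
                  position = length(ls(.classifiers)) + 1L),
         envir = .classifiers)
  invisible(id)
}

get_classifier <- function(id) {
  if (!exists(id, envir = .classifiers, inherits = FALSE))
    stop("unknown classifier id '", id, "'; see available_classifiers()",
         call. = FALSE)
  get(id, envir = .classifiers, inherits = FALSE)
}

#' List registered classifiers
#'
#' The mandatory families span linear, instance-based, Bayes, discriminant
#' and tree/boosting learners: logistic regression, decision tree, random
#' forest, adaptive boosting, gradient boosting, naive Bayes, k-nearest
#' neighbours, linear and quadratic discriminant analysis. Further families
#' can be added with [register_classifier()].
#'
#' @return data.frame `(id, label, supports_importance)` in registration
#'   order — the order also used as the deterministic model-selection
#'   tie-break.
#' @export
available_classifiers <- function() {
  ids <- ls(.classifiers)
  specs <- lapply(ids, get, envir = .classifiers)
  specs <- specs[order(vapply(specs, `[[`, integer(1), "position"))]
  data.frame(id = vapply(specs, `[[`, character(1), "id"),
             label = vapply(specs, `[[`, character(1), "label"),
             supports_importance = vapply(specs, `[[`, logical(1),
                                          "supports_importance"),
             stringsAsFactors = FALSE)
}

#' Ids of the mandatory classifier set
#' @return Character vector of registry ids.
#' @export
mandatory_classifiers <- function() {
  c("logistic_regression", "decision_tree", "random_forest",
    "adaptive_boosting", "gradient_boosting", "naive_bayes",
    "k_nearest_neighbours", "linear_discriminant", "quadratic_discriminant")
}

clamp01 <- function(p) pmin(pmax(as.numeric(p), 0), 1)

# drop columns that would make a (per-class) covariance singular: zero
# variance overall or within a class, then QR pivoting to a full-rank set
reduce_for_discriminant <- function(x, z, per_class = FALSE) {
  keep <- colnames(x)[apply(x, 2, stats::var) > 1e-10]
  if (per_class) {
    for (cls in c(0, 1)) {
      xs <- x[z == cls, keep, drop = FALSE]
      keep <- keep[apply(xs, 2, stats::var) > 1e-10]
    }
  }
  groups <- if (per_class) list(z == 0, z == 1) else list(rep(TRUE, nrow(x)))
  repeat {
    changed <- FALSE
    for (sel in groups) {
      xs <- scale(x[sel, keep, drop = FALSE], center = TRUE, scale = FALSE)
      qd <- qr(xs)
      if (qd$rank < length(keep)) {
        keep <- keep[sort(qd$pivot[seq_len(qd$rank)])]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  keep
}

register_default_classifiers <- function() {
  rm(list = ls(.classifiers), envir = .classifiers)

  register_classifier(
    "logistic_regression", "logistic regression",
    fit = function(x, z, hp) {
      df <- as.data.frame(x)
      df$.z <- z
      suppressWarnings(stats::glm(.z ~ ., data = df,
                                  family = stats::binomial()))
    },
    predict_prob = function(fitted, x) {
      clamp01(suppressWarnings(
        stats::predict(fitted, as.data.frame(x), type = "response")))
    })

  register_classifier(
    "decision_tree", "decision tree",
    fit = function(x, z, hp) {
      df <- as.data.frame(x)
      df$.z <- factor(z, levels = c(0, 1))
      rpart::rpart(.z ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     cp = hp$cp, minsplit = hp$minsplit, xval = 0))
    },
    predict_prob = function(fitted, x) {
      clamp01(predict(fitted, as.data.frame(x), type = "prob")[, "1"])
    },
    supports_importance = TRUE,
    importance = function(fitted) {
      vi <- fitted$variable.importance
      if (is.null(vi)) stop("tree has no splits; importance undefined",
                            call. = FALSE)
      vi
    },
    hyperparameters = list(cp = 0.01, minsplit = 20))

  register_classifier(
    "random_forest", "random forest",
    fit = function(x, z, hp) {
      randomForest::randomForest(x = x, y = factor(z, levels = c(0, 1)),
                                 ntree = hp$ntree)
    },
    predict_prob = function(fitted, x) {
      clamp01(predict(fitted, x, type = "prob")[, "1"])
    },
    supports_importance = TRUE,
    importance = function(fitted) {
      imp <- randomForest::importance(fitted, type = 2)
      stats::setNames(imp[, 1], rownames(imp))
    },
    hyperparameters = list(ntree = 500))

  register_classifier(
    "adaptive_boosting", "adaptive boosting",
    fit = function(x, z, hp) {
      adaboost_fit(x, z, n_trees = hp$n_trees, max_depth = hp$max_depth)
    },
    predict_prob = function(fitted, x) clamp01(predict(fitted, x)),
    supports_importance = TRUE,
    importance = function(fitted) {
      vi <- adaboost_importance(fitted)
      if (length(vi) == 0) stop("ensemble has no splits; importance undefined",
                                call. = FALSE)
      vi
    },
    hyperparameters = list(n_trees = 50, max_depth = 1))

  register_classifier(
    "gradient_boosting", "gradient boosting",
    fit = function(x, z, hp) {
      dtrain <- xgboost::xgb.DMatrix(data = x, label = z)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                      eta = hp$eta, nthread = 1),
        data = dtrain, nrounds = hp$nrounds, verbose = 0)
    },
    predict_prob = function(fitted, x) {
      clamp01(predict(fitted, xgboost::xgb.DMatrix(data = x)))
    },
    supports_importance = TRUE,
    importance = function(fitted) {
      imp <- xgboost::xgb.importance(model = fitted)
      stats::setNames(imp$Gain, imp$Feature)
    },
    hyperparameters = list(nrounds = 100, max_depth = 3, eta = 0.1))

  register_classifier(
    "naive_bayes", "naive Bayes",
    fit = function(x, z, hp) {
      e1071::naiveBayes(x = as.data.frame(x), y = factor(z, levels = c(0, 1)))
    },
    predict_prob = function(fitted, x) {
      clamp01(predict(fitted, as.data.frame(x), type = "raw",
                      eps = 1e-9, threshold = 1e-3)[, "1"])
    })

  register_classifier(
    "k_nearest_neighbours", "k-nearest neighbours",
    fit = function(x, z, hp) {
      caret::knn3(x = x, y = factor(z, levels = c(0, 1)),
                  k = min(hp$k, nrow(x) - 1))
    },
    predict_prob = function(fitted, x) {
      clamp01(predict(fitted, x, type = "prob")[, "1"])
    },
    hyperparameters = list(k = 5))

  register_classifier(
    "linear_discriminant", "linear discriminant analysis",
    fit = function(x, z, hp) {
      cols <- reduce_for_discriminant(x, z, per_class = FALSE)
      fit <- MASS::lda(x[, cols, drop = FALSE], grouping = factor(z))
      list(fit = fit, cols = cols)
    },
    predict_prob = function(fitted, x) {
      clamp01(predict(fitted$fit,
                      x[, fitted$cols, drop = FALSE])$posterior[, "1"])
    })

  register_classifier(
    "quadratic_discriminant", "quadratic discriminant analysis",
    fit = function(x, z, hp) {
      cols <- reduce_for_discriminant(x, z, per_class = TRUE)
      fit <- MASS::qda(x[, cols, drop = FALSE], grouping = factor(z))
      list(fit = fit, cols = cols)
    },
    predict_prob = function(fitted, x) {
      clamp01(predict(fitted$fit,
                      x[, fitted$cols, drop = FALSE])$posterior[, "1"])
    })
}
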