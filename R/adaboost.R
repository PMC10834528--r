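#' Discrete AdaBoost over classification stumps
#'
#' Adaptive boosting for a binary target: weighted rpart stumps are fitted
#' sequentially, each round up-weighting the observations the previous stump
#' misclassified. Class probabilities use the logistic link on the ensemble
#' margin, `P(z = 1 | x) = 1 / (1 + exp(-2 F(x)))` with
#' `F(x) = sum_m alpha_m h_m(x)`, `h_m in {-1, +1}`.
#'
#' @param x Numeric design matrix.
#' @param z Binary 0/1 target.
#' @param n_trees Number of boosting rounds (default 50).
#' @param max_depth Depth of each weak learner (default 1, a stump).
#' @return An `adaboost` object (list of stumps and their weights).
#' @export
adaboost_fit <- function(x, z, n_trees = 50, max_depth = 1) {
  stopifnot(is.matrix(x), all(z %in% c(0, 1)))
  n <- nrow(x)
  df <- as.data.frame(x)
  df$.z <- factor(z, levels = c(0, 1))
  y <- ifelse(z == 1, 1, -1)
  w <- rep(1 / n, n)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, minsplit = 2,
                               minbucket = 1, xval = 0, maxsurrogate = 0,
                               maxcompete = 0)
  trees <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_trees)) {
    fit <- rpart::rpart(.z ~ ., data = df, weights = w * n, method = "class",
                        control = ctrl)
    pred <- predict(fit, df, type = "class")
    h <- ifelse(pred == "1", 1, -1)
    err <- sum(w[h != y])
    if (err >= 0.5) break        # weak learner no better than chance: stop
    # cap the vote of a perfect stump instead of an infinite alpha
    alpha <- 0.5 * log((1 - max(err, 1e-10)) / max(err, 1e-10))
    trees[[length(trees) + 1]] <- fit
    alphas <- c(alphas, alpha)
    if (err <= 0) break
    w <- w * exp(-alpha * y * h)
    w <- w / sum(w)
  }
  if (length(trees) == 0) {
    # degenerate training set: fall back to the weighted class prior
    prior <- sum(w[z == 1])
    return(structure(list(trees = list(), alphas = numeric(0),
                          prior = prior), class = "adaboost"))
  }
  structure(list(trees = trees, alphas = alphas, prior = NULL),
            class = "adaboost")
}

#' Predict class-1 probabilities from an AdaBoost ensemble
#' @param object An `adaboost` fit.
#' @param x Design matrix with the training columns.
#' @param ... Unused.
#' @return Numeric probabilities in [0, 1].
#' @export
predict.adaboost <- function(object, x, ...) {
  if (length(object$trees) == 0)
    return(rep(object$prior, nrow(x)))
  df <- as.data.frame(x)
  score <- numeric(nrow(df))
  for (m in seq_along(object$trees)) {
    pred <- predict(object$trees[[m]], df, type = "class")
    score <- score + object$alphas[m] * ifelse(pred == "1", 1, -1)
  }
  1 / (1 + exp(-2 * score))
}

# impurity-decrease importance aggregated over stumps, weighted by alpha
adaboost_importance <- function(object) {
  out <- numeric(0)
  for (m in seq_along(object$trees)) {
    vi <- object$trees[[m]]$variable.importance
    if (is.null(vi)) next
    vi <- vi / sum(vi)
    for (nm in names(vi)) {
      prev <- if (nm %in% names(out)) out[[nm]] else 0
      out[nm] <- prev + object$alphas[m] * vi[[nm]]
    }
  }
  out
}
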