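#' Screen features by missingness
#'
#' A feature is dropped if and only if its missing fraction is strictly
#' greater than `threshold` ("more than 15%" by default), so a feature
#' missing in exactly 15% of rows is kept.
#'
#' @param cohort A `cohort_table`.
#' @param threshold Missing-fraction threshold in [0, 1]; default 0.15.
#' @return List with `kept` and `dropped` feature name vectors and the
#'   per-feature `missing_fraction`.
#' @export
screen_missingness <- function(cohort, threshold = 0.15) {
  stopifnot(inherits(cohort, "cohort_table"),
            threshold >= 0, threshold <= 1)
  n <- n_subjects(cohort)
  if (n == 0) stop("empty cohort", call. = FALSE)
  frac <- vapply(covariate_data(cohort), function(x) mean(is.na(x)),
                 numeric(1))
  list(kept = names(frac)[frac <= threshold],
       dropped = names(frac)[frac > threshold],
       missing_fraction = frac,
       threshold = threshold)
}

#' Fit imputation parameters on a training cohort
#'
#' Continuous features impute with the training mean of observed values;
#' categorical features impute with the constant level `"not available"`,
#' which is added to the level set and treated downstream as an ordinary
#' category.
#'
#' @param cohort Training `cohort_table`.
#' @param features Feature names to fit (default: all schema features).
#' @return Named list of imputation values.
#' @export
fit_impute <- function(cohort, features = names(cohort$schema)) {
  stopifnot(inherits(cohort, "cohort_table"))
  out <- list()
  for (f in features) {
    if (cohort$schema[[f]] == "continuous") {
      obs <- cohort$data[[f]][!is.na(cohort$data[[f]])]
      if (length(obs) == 0)
        stop("continuous feature '", f, "' has no observed training values",
             call. = FALSE)
      out[[f]] <- mean(obs)
    } else {
      out[[f]] <- "not available"
    }
  }
  out
}

#' Apply imputation values to a cohort
#'
#' Uses the training-fitted values only; never recomputes statistics on the
#' cohort being transformed.
#'
#' @param impute_values Output of [fit_impute()].
#' @param cohort A `cohort_table`.
#' @return The cohort with every fitted feature fully observed.
#' @export
apply_impute <- function(impute_values, cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- cohort$data
  for (f in names(impute_values)) {
    miss <- is.na(df[[f]])
    if (any(miss)) df[[f]][miss] <- impute_values[[f]]
  }
  cohort_table(df, cohort$schema, cohort$horizon)
}

# connected components of the |r| > threshold graph over continuous features
correlated_components <- function(cmat, r_threshold) {
  adj <- abs(cmat) > r_threshold
  diag(adj) <- FALSE
  nms <- rownames(cmat)
  comp <- rep(NA_integer_, length(nms))
  k <- 0
  for (i in seq_along(nms)) {
    if (!is.na(comp[i])) next
    k <- k + 1
    frontier <- i
    comp[i] <- k
    while (length(frontier) > 0) {
      nbrs <- which(adj[frontier[1], ] & is.na(comp))
      comp[nbrs] <- k
      frontier <- c(frontier[-1], nbrs)
    }
  }
  split(nms, comp)
}

#' Prune highly correlated continuous features
#'
#' Within each connected group of features whose pairwise Pearson |r|
#' strictly exceeds `r_threshold`, exactly one feature is kept: the one
#' ranked highest in the caller's `keep_priority` list. "Most informative"
#' is a clinical judgement, not a computable rule, so an automatic choice is
#' refused — if any correlated group exists and no listed feature resolves
#' it, the call errors and demands an explicit priority. Categorical
#' features are excluded (Pearson r is undefined for unordered levels).
#'
#' @param cohort A `cohort_table` whose continuous features are imputed.
#' @param r_threshold Correlation threshold; default 0.7, strict inequality.
#' @param keep_priority Ordered character vector: earlier names win.
#' @return List with `kept` (all surviving features, schema order, including
#'   categoricals) and `dropped` (data.frame `dropped`, `kept`, `r`).
#' @export
prune_correlated <- function(cohort, r_threshold = 0.7, keep_priority = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  cont <- names(cohort$schema)[cohort$schema == "continuous"]
  dropped <- data.frame(dropped = character(), kept = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  if (length(cont) >= 2) {
    x <- as.matrix(cohort$data[cont])
    if (anyNA(x))
      stop("continuous features must be imputed before pruning", call. = FALSE)
    cmat <- suppressWarnings(stats::cor(x))
    cmat[is.na(cmat)] <- 0  # zero-variance columns correlate with nothing
    comps <- correlated_components(cmat, r_threshold)
    for (grp in comps) {
      if (length(grp) < 2) next
      if (is.null(keep_priority))
        stop("correlated features ", paste(grp, collapse = ", "),
             " (|r| > ", r_threshold, "): supply an explicit keep_priority",
             call. = FALSE)
      pri <- match(grp, keep_priority)
      if (all(is.na(pri)))
        stop("no member of the correlated group ",
             paste(grp, collapse = ", "),
             " appears in keep_priority; refusing an automatic choice",
             call. = FALSE)
      winner <- grp[which.min(ifelse(is.na(pri), Inf, pri))]
      losers <- setdiff(grp, winner)
      dropped <- rbind(dropped, data.frame(
        dropped = losers, kept = winner,
        r = cmat[losers, winner], stringsAsFactors = FALSE))
    }
  }
  kept <- setdiff(names(cohort$schema), dropped$dropped)
  list(kept = kept, dropped = dropped, r_threshold = r_threshold)
}

#' Fit robust scaling parameters (median / interquartile range)
#'
#' Centers at the training median and scales by the training IQR (linear
#' interpolation, quantile type 7). A zero-IQR feature is passed through
#' centered only, with a warning.
#'
#' @param cohort Training `cohort_table` with continuous features imputed.
#' @param features Continuous features to fit (default: all).
#' @return Named list of `(center, spread)` pairs.
#' @export
fit_scale <- function(cohort,
                      features = names(cohort$schema)[cohort$schema == "continuous"]) {
  stopifnot(inherits(cohort, "cohort_table"))
  out <- list()
  for (f in features) {
    x <- cohort$data[[f]]
    if (anyNA(x)) stop("feature '", f, "' must be imputed before scaling",
                       call. = FALSE)
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    spread <- q[3] - q[1]
    if (spread == 0)
      warning("feature '", f, "' has zero interquartile range; ",
              "centering only", call. = FALSE)
    out[[f]] <- c(center = q[2], spread = spread)
  }
  out
}

#' Apply fitted scaling to a cohort
#' @param scale_params Output of [fit_scale()].
#' @param cohort A `cohort_table`.
#' @return The cohort with scaled continuous features.
#' @export
apply_scale <- function(scale_params, cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- cohort$data
  for (f in names(scale_params)) {
    p <- scale_params[[f]]
    df[[f]] <- if (p[["spread"]] == 0) df[[f]] - p[["center"]]
               else (df[[f]] - p[["center"]]) / p[["spread"]]
  }
  cohort_table(df, cohort$schema, cohort$horizon)
}

#' Fit the full preprocessing recipe on a training cohort
#'
#' Missingness screening, imputation, correlation pruning and robust scaling
#' in that order, all statistics computed on the training cohort only. The
#' returned recipe is a pure function of the training data: applying it
#' never reads statistics from the cohort being transformed, so held-out
#' data cannot leak into the preparation.
#'
#' @param cohort Training `cohort_table`.
#' @param missing_threshold Missing-fraction threshold (default 0.15).
#' @param r_threshold Correlation-pruning threshold (default 0.7).
#' @param keep_priority Ordered names resolving correlated groups; may be
#'   `NULL` when no group exists.
#' @return A `preprocess_recipe` object.
#' @export
fit_preprocess_recipe <- function(cohort, missing_threshold = 0.15,
                                  r_threshold = 0.7, keep_priority = NULL) {
  scr <- screen_missingness(cohort, missing_threshold)
  impute_values <- fit_impute(cohort, scr$kept)
  imputed <- apply_impute(impute_values, cohort)
  sub_schema <- cohort$schema[scr$kept]
  sub <- cohort_table(imputed$data[c("subject_id", "registration_order",
                                     "arm", "success", "event_time",
                                     "event_indicator", scr$kept)],
                      sub_schema, cohort$horizon)
  pr <- prune_correlated(sub, r_threshold, keep_priority)
  kept <- pr$kept
  cont_kept <- kept[sub_schema[kept] == "continuous"]
  keep_cohort <- cohort_table(sub$data, sub_schema, cohort$horizon)
  scale_params <- fit_scale(keep_cohort, cont_kept)
  structure(list(kept_features = kept,
                 dropped_missingness = scr$dropped,
                 missing_threshold = missing_threshold,
                 dropped_correlated = pr$dropped,
                 r_threshold = r_threshold,
                 impute_values = impute_values[kept],
                 scale_params = scale_params,
                 schema = cohort$schema[kept]),
            class = "preprocess_recipe")
}

#' @export
print.preprocess_recipe <- function(x, ...) {
  cat("preprocess_recipe:", length(x$kept_features), "features kept\n")
  if (length(x$dropped_missingness) > 0)
    cat("  dropped for missingness >", x$missing_threshold, ":",
        paste(x$dropped_missingness, collapse = ", "), "\n")
  if (nrow(x$dropped_correlated) > 0)
    for (i in seq_len(nrow(x$dropped_correlated)))
      cat(sprintf("  dropped %s (|r| = %.3f with %s)\n",
                  x$dropped_correlated$dropped[i],
                  abs(x$dropped_correlated$r[i]),
                  x$dropped_correlated$kept[i]))
  invisible(x)
}

#' Apply a fitted recipe to any schema-conforming cohort
#'
#' @param recipe A `preprocess_recipe`.
#' @param cohort A `cohort_table` sharing the training schema.
#' @return A `cohort_table` restricted to kept features, imputed and scaled.
#' @export
apply_recipe <- function(recipe, cohort) {
  stopifnot(inherits(recipe, "preprocess_recipe"),
            inherits(cohort, "cohort_table"))
  missing_feat <- setdiff(recipe$kept_features, names(cohort$data))
  if (length(missing_feat) > 0)
    stop("schema mismatch: cohort lacks feature(s) ",
         paste(missing_feat, collapse = ", "), call. = FALSE)
  df <- cohort$data[c("subject_id", "registration_order", "arm", "success",
                      "event_time", "event_indicator", recipe$kept_features)]
  out <- cohort_table(df, recipe$schema, cohort$horizon)
  out <- apply_impute(recipe$impute_values, out)
  apply_scale(recipe$scale_params, out)
}

#' Serialize a recipe to JSON
#' @param recipe A `preprocess_recipe`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recipe <- function(recipe, path) {
  jsonlite::write_json(
    list(kept_features = recipe$kept_features,
         dropped_missingness = recipe$dropped_missingness,
         missing_threshold = recipe$missing_threshold,
         dropped_correlated = recipe$dropped_correlated,
         r_threshold = recipe$r_threshold,
         impute_values = recipe$impute_values,
         scale_params = lapply(recipe$scale_params, as.list),
         schema = as.list(recipe$schema)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
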