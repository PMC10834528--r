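#' Stratify subjects by uplift-score cutoff
#'
#' The high stratum is closed at the cutoff (`score >= cutoff`), matching the
#' convention of labeling the benefit group "uplift score >= phi*".
#'
#' @param scores Numeric uplift scores.
#' @param cutoff Numeric cutoff on the same scale.
#' @return Factor with levels `c("low", "high")`.
#' @export
stratify_by_cutoff <- function(scores, cutoff) {
  stopifnot(is.numeric(scores), is.numeric(cutoff), length(cutoff) == 1)
  factor(ifelse(scores >= cutoff, "high", "low"), levels = c("low", "high"))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Probability-summation definition: the p-value sums hypergeometric
#' probabilities of all tables no more likely than the observed one (the
#' convention of standard statistical software; mid-p and CI-based variants
#' differ).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(table) == 0) stop("empty table", call. = FALSE)
  stats::fisher.test(table)$p.value
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration of rank splits when the combined sample size is at most
#' 20 and there are no ties; otherwise the normal approximation with tie
#' correction (no continuity correction, so identical samples give p = 1).
#'
#' @param x,y Non-empty numeric samples.
#' @return Two-sided p-value.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  p <- if (!ties && length(x) + length(y) <= 20) {
    stats::wilcox.test(x, y, exact = TRUE)$p.value
  } else {
    suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
  }
  if (is.nan(p)) p <- 1  # zero-variance rank statistic: no evidence either way
  min(p, 1)
}

#' Kaplan-Meier product-limit estimate
#'
#' Censored subjects leave the risk set without contributing a step.
#'
#' @param times Positive event/censoring times (months).
#' @param events Binary: 1 = event observed at `times`, 0 = censored.
#' @return A `km_curve` data.frame `(time, n_risk, n_event, survival)`
#'   beginning at the implicit (0, 1); attribute `n`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, survival = fit$surv)
  attr(out, "n") <- length(times)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param km A `km_curve`.
#' @param t Times at which to read the step function.
#' @return Survival probabilities.
#' @export
km_at <- function(km, t) {
  stopifnot(inherits(km, "km_curve"))
  vapply(t, function(tt) {
    idx <- which(km$time <= tt)
    if (length(idx) == 0) 1 else km$survival[max(idx)]
  }, numeric(1))
}

#' Unadjusted Cox hazard ratio of treatment within a stratum
#'
#' Partial-likelihood fit with Efron handling of tied event times; reports
#' the treatment hazard ratio (treatment vs control), Wald 95% CI and
#' p-value, and the log-rank p-value alongside. Complete separation
#' (monotone likelihood) is flagged with a warning.
#'
#' @param times Positive event/censoring times.
#' @param events Binary event indicators.
#' @param arm `"treatment"`/`"control"` per subject.
#' @return A `cox_hr` list: `hazard_ratio`, `ci95`, `cox_p`, `logrank_p`,
#'   `n`, `n_events`, per-arm counts, and the underlying `fit`.
#' @export
cox_treatment_hr <- function(times, events, arm) {
  stopifnot(length(times) == length(events), length(arm) == length(times),
            all(arm %in% c("treatment", "control")))
  if (!any(arm == "treatment") || !any(arm == "control"))
    stop("both arms must be present", call. = FALSE)
  if (sum(events) < 1) stop("no events: hazard ratio undefined", call. = FALSE)
  arm_f <- factor(arm, levels = c("control", "treatment"))
  fit <- survival::coxph(survival::Surv(times, events) ~ arm_f,
                         ties = "efron")
  sm <- summary(fit)
  beta <- sm$coefficients[1, "coef"]
  se <- sm$coefficients[1, "se(coef)"]
  if (!is.finite(se) || se > 10)
    warning("monotone likelihood (complete separation) suspected; ",
            "hazard ratio unreliable", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(times, events) ~ arm_f)
  structure(list(
    hazard_ratio = exp(beta),
    ci95 = c(exp(beta - 1.96 * se), exp(beta + 1.96 * se)),
    cox_p = sm$coefficients[1, "Pr(>|z|)"],
    logrank_p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
    n = length(times), n_events = sum(events),
    per_arm = data.frame(
      arm = c("control", "treatment"),
      n = c(sum(arm == "control"), sum(arm == "treatment")),
      events = c(sum(events[arm == "control"]),
                 sum(events[arm == "treatment"]))),
    fit = fit), class = "cox_hr")
}

#' @export
print.cox_hr <- function(x, ...) {
  cat(sprintf("HR %.2f; 95%% CI %.2f-%.2f; Cox P = %.3f; log-rank P = %.3f\n",
              x$hazard_ratio, x$ci95[1], x$ci95[2], x$cox_p, x$logrank_p))
  invisible(x)
}

#' Treatment-by-stratum interaction in a Cox model
#'
#' Fits `Surv ~ treatment + stratum + treatment:stratum` and reports the
#' Wald p-value of the product term — the test of whether the treatment
#' effect differs between the uplift-score strata.
#'
#' @param times,events Survival outcome per subject.
#' @param arm `"treatment"`/`"control"` per subject.
#' @param stratum `"high"`/`"low"` (or any two labels) per subject.
#' @return An `interaction_result` list: `interaction_p`, per-term
#'   coefficient table, the `fit`.
#' @export
cox_interaction <- function(times, events, arm, stratum) {
  stopifnot(length(arm) == length(times), length(stratum) == length(times))
  tab <- table(arm, stratum)
  if (any(dim(tab) < 2) || any(tab == 0))
    stop("all arm-by-stratum cells must be non-empty", call. = FALSE)
  arm_f <- factor(arm, levels = c("control", "treatment"))
  str_f <- factor(stratum)
  fit <- survival::coxph(survival::Surv(times, events) ~ arm_f * str_f,
                         ties = "efron")
  sm <- summary(fit)$coefficients
  structure(list(interaction_p = sm[nrow(sm), "Pr(>|z|)"],
                 terms = sm, fit = fit),
            class = "interaction_result")
}

#' Proportional-hazards diagnostic from scaled Schoenfeld residuals
#'
#' Tests, per model term, the correlation of scaled Schoenfeld residuals
#' with time; a small p-value indicates a time-varying effect, i.e. a
#' proportional-hazards violation.
#'
#' @param fit A fitted `coxph` model (or a `cox_hr` result).
#' @param alpha Pass/fail level (default 0.05; pass means p > alpha).
#' @return data.frame `(term, chisq, df, p, pass)` including the GLOBAL row.
#' @export
schoenfeld_check <- function(fit, alpha = 0.05) {
  if (inherits(fit, "cox_hr")) fit <- fit$fit
  stopifnot(inherits(fit, "coxph"))
  if (fit$nevent < 2)
    stop("at least two events required for the Schoenfeld check",
         call. = FALSE)
  zph <- survival::cox.zph(fit)
  tab <- as.data.frame(zph$table)
  data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df,
             p = tab$p, pass = tab$p > alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Arm-vs-arm outcome comparison within one stratum
#'
#' Per-arm counts, event fractions and Kaplan-Meier curves plus the log-rank
#' p and unadjusted Cox treatment hazard ratio.
#'
#' @param times,events,arm Survival outcome and randomized arm per subject
#'   in the stratum.
#' @param stratum Label carried through reports (`"high"`/`"low"`).
#' @return A `stratum_comparison` list.
#' @export
stratum_comparison <- function(times, events, arm, stratum = NA_character_) {
  hr <- cox_treatment_hr(times, events, arm)
  km <- lapply(c(control = "control", treatment = "treatment"), function(a) {
    km_estimate(times[arm == a], events[arm == a])
  })
  structure(list(stratum = stratum,
                 per_arm = transform(
                   hr$per_arm, event_fraction = events / n),
                 km_curves = km,
                 hazard_ratio = hr$hazard_ratio,
                 ci95 = hr$ci95, cox_p = hr$cox_p,
                 logrank_p = hr$logrank_p,
                 fit = hr$fit),
            class = "stratum_comparison")
}

#' @export
print.stratum_comparison <- function(x, ...) {
  cat("stratum:", x$stratum, "\n")
  for (i in 1:2)
    cat(sprintf("  %s: %d/%d events (%.1f%%)\n", x$per_arm$arm[i],
                x$per_arm$events[i], x$per_arm$n[i],
                100 * x$per_arm$event_fraction[i]))
  cat(sprintf("  HR %.2f (95%% CI %.2f-%.2f), Cox P = %.3f, log-rank P = %.3f\n",
              x$hazard_ratio, x$ci95[1], x$ci95[2], x$cox_p, x$logrank_p))
  invisible(x)
}

#' Baseline-characteristics table between two groups
#'
#' Continuous features render as `median [Q1, Q3]` per group with a
#' Mann-Whitney p-value; categorical features as `n (%)` of the positive
#' level with a Fisher exact p-value (multi-level features get one row per
#' non-reference level, sharing the overall Fisher p). Optionally appends a
#' recurrence-outcome row from the event indicator.
#'
#' @param cohort A `cohort_table`.
#' @param grouping Factor/vector of exactly two group labels, one per
#'   subject.
#' @param features Features to tabulate (default: full schema).
#' @param include_outcome Append the recurrence row? Default `TRUE`.
#' @param positive_levels Levels counted as positive findings for binary
#'   categoricals.
#' @return data.frame `(feature, type, <group1>, <group2>, p_value)`.
#' @export
characteristics_table <- function(cohort, grouping,
                                  features = names(cohort$schema),
                                  include_outcome = TRUE,
                                  positive_levels = c("yes", "1", "TRUE")) {
  stopifnot(inherits(cohort, "cohort_table"),
            length(grouping) == n_subjects(cohort))
  grouping <- as.factor(as.character(grouping))
  if (nlevels(grouping) != 2)
    stop("grouping must define exactly two groups", call. = FALSE)
  g1 <- levels(grouping)[1]; g2 <- levels(grouping)[2]
  rows <- list()
  add_row <- function(feature, type, v1, v2, p) {
    rows[[length(rows) + 1]] <<- data.frame(
      feature = feature, type = type, g1 = v1, g2 = v2, p_value = p,
      stringsAsFactors = FALSE)
  }
  n1 <- sum(grouping == g1); n2 <- sum(grouping == g2)
  add_row("N", "count", as.character(n1), as.character(n2), NA_real_)

  for (f in features) {
    x <- cohort$data[[f]]
    if (cohort$schema[[f]] == "continuous") {
      x1 <- x[grouping == g1]; x2 <- x[grouping == g2]
      p <- if (all(is.na(x1)) || all(is.na(x2))) NA_real_
           else mann_whitney_u(x1, x2)
      add_row(f, "continuous", format_median_iqr(x1), format_median_iqr(x2), p)
    } else {
      obs <- !is.na(x)
      lev <- sort(unique(x[obs]))
      if (length(lev) < 2) {
        pos <- intersect(positive_levels, lev)
        pos <- if (length(pos) > 0) pos[1] else lev[1]
        add_row(f, "categorical",
                format_count_pct(sum(x[grouping == g1] == pos, na.rm = TRUE), n1),
                format_count_pct(sum(x[grouping == g2] == pos, na.rm = TRUE), n2),
                NA_real_)
        next
      }
      tab <- table(factor(x[obs], levels = lev),
                   factor(grouping[obs], levels = c(g1, g2)))
      p <- if (any(colSums(tab) == 0)) NA_real_
           else stats::fisher.test(tab)$p.value
      pos_lev <- intersect(positive_levels, lev)
      report_lev <- if (length(lev) == 2 && length(pos_lev) == 1) pos_lev
                    else lev[-1]
      for (l in report_lev) {
        nm <- if (length(report_lev) == 1) f else paste0(f, " = ", l)
        add_row(nm, "categorical",
                format_count_pct(tab[l, g1], n1),
                format_count_pct(tab[l, g2], n2), p)
      }
    }
  }

  if (include_outcome) {
    ev <- cohort$data$event_indicator
    tab <- table(factor(ev, levels = c(0, 1)), grouping)
    p <- stats::fisher.test(tab)$p.value
    add_row("recurrence_of_af", "outcome",
            format_count_pct(tab["1", g1], n1),
            format_count_pct(tab["1", g2], n2), p)
  }
  out <- do.call(rbind, rows)
  names(out)[3:4] <- c(g1, g2)
  out
}
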