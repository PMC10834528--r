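#' Configuration for the synthetic two-arm ablation trial generator
#'
#' The defaults emulate a persistent atrial-fibrillation ablation trial:
#' roughly 500 subjects, 1:1 allocation, control-arm 1-year success around
#' 74% (i.e. 20-30% recurrence), a mix of roughly normal clinical measures,
#' right-skewed laboratory values, and binary history items at realistic
#' prevalences, with missingness injected completely at random.
#'
#' The planted treatment benefit is covariate-dependent: the control-arm
#' success probability is `plogis(baseline_logit + eta)` with `eta` a linear
#' combination of standardized covariates (`nuisance_coefficients`), and the
#' treated-arm probability is `plogis(baseline_logit + eta + benefit)` with
#' `benefit = benefit_scale *` the `benefit_coefficients` combination. The
#' per-subject true uplift is the difference of the two probabilities, so it
#' is bounded in [-1, 1] by construction without clipping.
#'
#' @param n Number of subjects (>= 4).
#' @param continuous_features data.frame with columns `name`, `dist`
#'   (`"normal"` or `"lognormal"`), `p1`, `p2` (mean/sd, or meanlog/sdlog).
#' @param binary_features data.frame with columns `name`, `prevalence`.
#'   Binary features enter the cohort as categorical `"yes"`/`"no"`.
#' @param baseline_logit Intercept of the control-arm success logit.
#' @param nuisance_coefficients Named numeric: control-arm prognostic effects
#'   on standardized covariates.
#' @param benefit_coefficients Named numeric: direction of the planted uplift.
#' @param benefit_scale Non-negative multiplier on the benefit combination;
#'   0 removes all treatment-effect heterogeneity (and all benefit).
#' @param missingness_rates Named numeric in [0, 0.5): per-feature MCAR
#'   missingness probabilities.
#' @param censor_horizon Administrative censoring time in months (default 12).
#' @param time_model `"uniform"` (recurrence times uniform on (0, horizon])
#'   or `"exponential"` (constant hazard inverted to hit the subject's
#'   1-year failure probability; supports hazard-ratio recovery checks).
#' @param seed Integer seed; the generator is fully reproducible given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n = 500,
                             continuous_features = default_continuous_features(),
                             binary_features = default_binary_features(),
                             baseline_logit = stats::qlogis(0.74),
                             nuisance_coefficients = c(
                               age = -0.15,
                               left_ventricular_ejection_fraction = 0.15,
                               left_atrial_diameter = -0.20,
                               brain_natriuretic_peptide = -0.20,
                               long_standing_af = -0.30,
                               heart_failure = -0.20),
                             benefit_coefficients = c(
                               female_sex = 0.8,
                               smoking_history = -0.6,
                               hemoglobin = -0.4,
                               brain_natriuretic_peptide = -0.3,
                               left_atrial_diameter = 0.4),
                             benefit_scale = 1,
                             missingness_rates = c(
                               brain_natriuretic_peptide = 0.05,
                               c_reactive_protein = 0.08,
                               left_atrial_diameter = 0.03,
                               sleep_apnea_syndrome = 0.02),
                             censor_horizon = 12,
                             time_model = c("uniform", "exponential"),
                             seed = 1) {
  time_model <- match.arg(time_model)
  if (n < 4) stop("n must be >= 4", call. = FALSE)
  if (benefit_scale < 0) stop("benefit_scale must be >= 0", call. = FALSE)
  if (any(binary_features$prevalence <= 0 | binary_features$prevalence >= 1))
    stop("prevalences must lie in (0, 1)", call. = FALSE)
  if (length(missingness_rates) > 0 &&
      (any(missingness_rates < 0) || any(missingness_rates >= 0.5)))
    stop("missingness_rates must lie in [0, 0.5)", call. = FALSE)
  feat_names <- c(continuous_features$name, binary_features$name)
  if (anyDuplicated(feat_names)) stop("duplicate feature names", call. = FALSE)
  for (nm in list(nuisance_coefficients, benefit_coefficients,
                  missingness_rates)) {
    bad <- setdiff(names(nm), feat_names)
    if (length(bad) > 0)
      stop("coefficient/missingness names not in feature set: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(n = as.integer(n),
                 continuous_features = continuous_features,
                 binary_features = binary_features,
                 baseline_logit = baseline_logit,
                 nuisance_coefficients = nuisance_coefficients,
                 benefit_coefficients = benefit_coefficients,
                 benefit_scale = benefit_scale,
                 missingness_rates = missingness_rates,
                 censor_horizon = censor_horizon,
                 time_model = time_model,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default continuous covariate distributions
#'
#' Clinical measures roughly normal; labs with right-skewed marginals
#' (natriuretic peptide, creatinine, C-reactive protein) log-normal.
#' @return data.frame(name, dist, p1, p2).
#' @export
default_continuous_features <- function() {
  data.frame(
    name = c("age", "body_mass_index", "hemoglobin",
             "left_ventricular_ejection_fraction", "left_atrial_diameter",
             "brain_natriuretic_peptide", "creatinine", "c_reactive_protein"),
    dist = c("normal", "normal", "normal", "normal", "normal",
             "lognormal", "lognormal", "lognormal"),
    p1 = c(66, 24.5, 14.5, 63, 42, log(145), log(0.88), log(0.10)),
    p2 = c(9, 3.4, 1.4, 8, 4.5, 0.65, 0.22, 0.9),
    stringsAsFactors = FALSE)
}

#' Default binary covariate prevalences
#' @return data.frame(name, prevalence).
#' @export
default_binary_features <- function() {
  data.frame(
    name = c("female_sex", "long_standing_af", "hypertension",
             "diabetes_mellitus", "dyslipidemia", "smoking_history",
             "heart_failure", "family_history_af", "sleep_apnea_syndrome",
             "stroke_thromboembolism", "thyroid_disease", "copd",
             "liver_disease", "antiarrhythmic_history"),
    prevalence = c(0.25, 0.25, 0.60, 0.17, 0.46, 0.61, 0.19, 0.08, 0.11,
                   0.08, 0.05, 0.04, 0.05, 0.24),
    stringsAsFactors = FALSE)
}

# standardize a feature matrix column against its configured distribution so
# coefficients are on a comparable scale; binary features use (x-p)/sqrt(pq)
standardize_features <- function(values, config) {
  z <- list()
  cf <- config$continuous_features
  for (i in seq_len(nrow(cf))) {
    x <- values[[cf$name[i]]]
    z[[cf$name[i]]] <- if (cf$dist[i] == "lognormal") {
      (log(x) - cf$p1[i]) / cf$p2[i]
    } else {
      (x - cf$p1[i]) / cf$p2[i]
    }
  }
  bf <- config$binary_features
  for (i in seq_len(nrow(bf))) {
    p <- bf$prevalence[i]
    z[[bf$name[i]]] <- (values[[bf$name[i]]] - p) / sqrt(p * (1 - p))
  }
  z
}

#' Generate a synthetic randomized cohort with known treatment benefit
#'
#' Allocation is blocked randomization to an exact (or, for odd `n`, within
#' one) 1:1 split, drawn independently of the covariates. Subjects with
#' `success = 0` receive a recurrence time on (0, horizon] (uniform, or
#' exponential in the `"exponential"` time model); successes are
#' administratively censored at the horizon. Missingness is injected
#' completely at random per feature after outcomes are drawn, so the ground
#' truth reflects the complete covariates.
#'
#' @param config A [synthetic_config()].
#' @return List with `cohort` (a [cohort_table()]) and `truth` (data.frame
#'   `subject_id`, `true_uplift`, `p_control`, `p_treatment`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n

  values <- list()
  cf <- config$continuous_features
  for (i in seq_len(nrow(cf))) {
    values[[cf$name[i]]] <- if (cf$dist[i] == "lognormal") {
      stats::rlnorm(n, cf$p1[i], cf$p2[i])
    } else {
      stats::rnorm(n, cf$p1[i], cf$p2[i])
    }
  }
  bf <- config$binary_features
  for (i in seq_len(nrow(bf))) {
    values[[bf$name[i]]] <- stats::rbinom(n, 1, bf$prevalence[i])
  }

  z <- standardize_features(values, config)
  lincomb <- function(coefs) {
    out <- numeric(n)
    for (nm in names(coefs)) out <- out + coefs[[nm]] * z[[nm]]
    out
  }
  eta <- config$baseline_logit + lincomb(config$nuisance_coefficients)
  benefit <- config$benefit_scale * lincomb(config$benefit_coefficients)
  p_control <- stats::plogis(eta)
  p_treatment <- stats::plogis(eta + benefit)
  true_uplift <- p_treatment - p_control

  # blocked 1:1 allocation, independent of X: permute a balanced label vector
  arm_pool <- rep(c("treatment", "control"), length.out = n)
  arm <- sample(arm_pool)
  p_success <- ifelse(arm == "treatment", p_treatment, p_control)

  horizon <- config$censor_horizon
  if (config$time_model == "uniform") {
    success <- stats::rbinom(n, 1, p_success)
    event_time <- ifelse(success == 1, horizon,
                         horizon * stats::runif(n, min = .Machine$double.eps))
    event_indicator <- 1L - success
  } else {
    # constant hazard chosen so P(no event by horizon) = p_success exactly
    lambda <- -log(pmin(pmax(p_success, 1e-12), 1 - 1e-12)) / horizon
    t_event <- stats::rexp(n, rate = lambda)
    event_indicator <- as.integer(t_event <= horizon)
    event_time <- pmin(t_event, horizon)
    event_time[event_time <= 0] <- .Machine$double.eps
    success <- 1L - event_indicator
  }

  df <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                   registration_order = seq_len(n),
                   arm = arm, success = as.integer(success),
                   event_time = event_time,
                   event_indicator = as.integer(event_indicator),
                   stringsAsFactors = FALSE)
  schema <- c(stats::setNames(rep("continuous", nrow(cf)), cf$name),
              stats::setNames(rep("categorical", nrow(bf)), bf$name))
  for (nm in cf$name) df[[nm]] <- values[[nm]]
  for (nm in bf$name) df[[nm]] <- ifelse(values[[nm]] == 1, "yes", "no")

  # MCAR missingness, injected last
  for (nm in names(config$missingness_rates)) {
    rate <- config$missingness_rates[[nm]]
    if (rate > 0) {
      hit <- stats::runif(n) < rate
      df[[nm]][hit] <- NA
    }
  }

  truth <- data.frame(subject_id = df$subject_id,
                      true_uplift = true_uplift,
                      p_control = p_control,
                      p_treatment = p_treatment,
                      stringsAsFactors = FALSE)
  list(cohort = cohort_table(df, schema, horizon), truth = truth)
}

#' Empirical uplift within strata
#'
#' For each stratum, the treated success fraction minus the control success
#' fraction — the finite-sample analogue of the uplift estimand
#' `P_T(Y=1|X) - P_C(Y=1|X)`, and the oracle against which the
#' `2 P(Z=1|X) - 1` identity is checked.
#'
#' @param cohort A `cohort_table`.
#' @param strata Vector (factor or character) of stratum labels, one per
#'   subject in cohort order.
#' @return Named numeric of per-stratum empirical uplift.
#' @export
empirical_uplift_by_stratum <- function(cohort, strata) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (length(strata) != n_subjects(cohort))
    stop("strata must have one label per subject", call. = FALSE)
  strata <- as.character(strata)
  out <- vapply(unique(strata), function(s) {
    sel <- strata == s
    arm <- cohort$data$arm[sel]
    y <- cohort$data$success[sel]
    if (!any(arm == "treatment") || !any(arm == "control"))
      stop("stratum '", s, "' lacks subjects in one arm", call. = FALSE)
    mean(y[arm == "treatment"]) - mean(y[arm == "control"])
  }, numeric(1))
  out
}
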