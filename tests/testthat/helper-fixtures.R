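# Fixtures are built in code: a minimal hand-specified cohort constructor and
# independent oracles for the Qini machinery.

# cohort with one continuous and one categorical covariate, outcomes supplied
make_cohort <- function(arm, success, x = seq_along(arm),
                        grp = rep("a", length(arm)), horizon = 12) {
  n <- length(arm)
  event_indicator <- 1L - as.integer(success)
  df <- data.frame(
    subject_id = sprintf("P%03d", seq_len(n)),
    registration_order = seq_len(n),
    arm = arm,
    success = as.integer(success),
    event_time = ifelse(event_indicator == 1, horizon / 2, horizon),
    event_indicator = event_indicator,
    x = as.numeric(x),
    grp = as.character(grp),
    stringsAsFactors = FALSE)
  cohort_table(df, c(x = "continuous", grp = "categorical"), horizon)
}

# independent Qini oracle: for every distinct threshold, subset score >= phi
# and apply the formula directly (no cumulative sums shared with the
# implementation)
oracle_qini <- function(scores, arms, successes) {
  phis <- sort(unique(scores), decreasing = TRUE)
  rows <- lapply(phis, function(phi) {
    sel <- scores >= phi
    s_t <- sum(successes[sel & arms == "treatment"])
    s_c <- sum(successes[sel & arms == "control"])
    n_t <- sum(sel & arms == "treatment")
    n_c <- sum(sel & arms == "control")
    q <- if (n_c == 0) s_t else s_t - s_c * n_t / n_c
    data.frame(rank = sum(sel), threshold_phi = phi, s_t = s_t, s_c = s_c,
               n_t = n_t, n_c = n_c, qini_value = q)
  })
  out <- do.call(rbind, rows)
  final_q <- out$qini_value[nrow(out)]
  out$diagonal_value <- out$rank / length(scores) * final_q
  out
}

# trapezoid oracle over the oracle curve (prepending the origin)
oracle_qini_area <- function(scores, arms, successes) {
  oc <- oracle_qini(scores, arms, successes)
  x <- c(0, oc$rank)
  d <- c(0, oc$qini_value - oc$diagonal_value)
  pracma::trapz(x, d)
}

# cohort with a single continuous covariate missing in the first n_missing rows
make_missing_cohort <- function(n_missing, n = 100) {
  arm <- rep(c("treatment", "control"), n / 2)
  cohort <- make_cohort(arm, rep(c(1, 0), n / 2), x = rnorm(n))
  cohort$data$x[seq_len(n_missing)] <- NA
  cohort
}

# cohort made of the supplied continuous columns only
make_multi_cohort <- function(cols) {
  n <- length(cols[[1]])
  df <- data.frame(
    subject_id = sprintf("S%02d", 1:n), registration_order = 1:n,
    arm = rep(c("treatment", "control"), length.out = n),
    event_time = rep(12, n), event_indicator = rep(0, n),
    stringsAsFactors = FALSE)
  for (nm in names(cols)) df[[nm]] <- cols[[nm]]
  cohort_table(df, setNames(rep("continuous", length(cols)), names(cols)))
}

# small synthetic cohort for classifier contract checks
contract_cohort <- function(n = 40, seed = 11) {
  cfg <- synthetic_config(
    n = n,
    continuous_features = data.frame(
      name = c("a", "b"), dist = "normal", p1 = c(0, 5), p2 = c(1, 2),
      stringsAsFactors = FALSE),
    binary_features = data.frame(name = "f", prevalence = 0.4,
                                 stringsAsFactors = FALSE),
    nuisance_coefficients = c(a = 0.8),
    benefit_coefficients = c(b = 0.8),
    missingness_rates = numeric(0),
    seed = seed)
  generate_cohort(cfg)
}
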