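test_that("cutoff stratification is closed on the high side", {
  s <- c(0.0124, 0.0123, 0.5, -0.2)
  f <- stratify_by_cutoff(s, 0.0124)
  expect_equal(as.character(f), c("high", "low", "high", "low"))
  expect_equal(nlevels(f), 2)
  all_low <- stratify_by_cutoff(c(-0.5, -0.1), 0.0124)
  expect_equal(sum(all_low == "high"), 0)
})

test_that("Fisher exact p is the probability-summation two-sided value", {
  sym <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(fisher_exact_2x2(sym), 1)
  tab <- matrix(c(12, 3, 4, 11), 2)
  expect_equal(fisher_exact_2x2(tab), fisher_exact_2x2(t(tab)))
  # swapping rows with columns leaves p unchanged
  expect_equal(fisher_exact_2x2(tab), fisher_exact_2x2(tab[2:1, ]))
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("Mann-Whitney uses exact enumeration at desk scale", {
  # all C(4,2) = 6 rank splits: the observed extreme split has
  # one-sided probability 1/6, two-sided 1/3
  expect_equal(mann_whitney_u(c(1, 2), c(10, 20)), 1 / 3)
  expect_equal(mann_whitney_u(c(5, 5, 5), c(5, 5, 5)), 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
  # agreement with the normal approximation at larger n
  set.seed(21)
  x <- rnorm(40); y <- rnorm(45, 0.5)
  expect_equal(mann_whitney_u(x, y),
               wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
})

test_that("null Mann-Whitney p-values are approximately uniform", {
  set.seed(22)
  ps <- replicate(400, mann_whitney_u(rnorm(30), rnorm(35)))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km0 <- km_estimate(c(3, 6, 12), c(0, 0, 0))
  expect_true(all(km0$survival == 1))

  km3 <- km_estimate(c(2, 5, 9), c(1, 1, 1))
  expect_equal(km3$survival, c(2 / 3, 1 / 3, 0))

  # mixed censoring, hand oracle over risk sets:
  # t=1 event (6 at risk) -> 5/6; t=2 censor; t=3 event (4 at risk) -> 5/6*3/4
  # t=4 event (3 at risk) -> *2/3; t=5 censor; t=6 event (1 at risk) -> 0
  km6 <- km_estimate(c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 1, 0, 1))
  expect_equal(km_at(km6, c(1, 3, 4, 6)),
               c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3, 0))

  # without censoring the estimate is the empirical survival function
  set.seed(23)
  t <- rexp(200)
  km <- km_estimate(t, rep(1, 200))
  grid <- quantile(t, c(0.2, 0.5, 0.8))
  expect_equal(km_at(km, grid), sapply(grid, function(g) mean(t > g)))
})

test_that("Cox recovers a known hazard ratio and behaves at the null", {
  set.seed(24)
  n <- 5000
  arm <- rep(c("treatment", "control"), n / 2)
  lam <- ifelse(arm == "treatment", 0.2, 0.1)
  t <- rexp(n, lam)
  events <- as.integer(t <= 12)
  times <- pmin(t, 12)
  hr <- cox_treatment_hr(times, events, arm)
  expect_gt(hr$hazard_ratio, 1.8)
  expect_lt(hr$hazard_ratio, 2.2)
  expect_true(hr$ci95[1] < hr$hazard_ratio & hr$hazard_ratio < hr$ci95[2])

  # identical arms: HR near 1, CI covering 1
  null_hr <- cox_treatment_hr(times, events,
                              sample(arm))
  expect_lt(abs(log(null_hr$hazard_ratio)), 0.2)
  expect_true(null_hr$ci95[1] < 1 & null_hr$ci95[2] > 1)

  expect_error(cox_treatment_hr(c(1, 2), c(0, 0), c("treatment", "control")),
               "no events")
})

test_that("duplicating every subject keeps the HR but narrows the CI", {
  set.seed(25)
  n <- 400
  arm <- rep(c("treatment", "control"), n / 2)
  t <- rexp(n, ifelse(arm == "treatment", 0.15, 0.1))
  events <- as.integer(t <= 12)
  times <- pmin(t, 12)
  one <- cox_treatment_hr(times, events, arm)
  two <- cox_treatment_hr(rep(times, 2), rep(events, 2), rep(arm, 2))
  # duplication introduces ties; Efron's correction shifts the estimate
  # only marginally
  expect_equal(two$hazard_ratio, one$hazard_ratio, tolerance = 0.005)
  expect_lt(diff(log(two$ci95)), diff(log(one$ci95)))
})

test_that("interaction p is calibrated under the null and powered under heterogeneity", {
  set.seed(26)
  null_ps <- replicate(120, {
    n <- 400
    arm <- sample(rep(c("treatment", "control"), n / 2))
    stratum <- sample(rep(c("high", "low"), n / 2))
    t <- rexp(n, 0.08)
    cox_interaction(pmin(t, 12), as.integer(t <= 12), arm, stratum)$interaction_p
  })
  expect_gt(suppressWarnings(ks.test(null_ps, "punif"))$p.value, 0.01)

  power_ps <- replicate(30, {
    n <- 800
    arm <- sample(rep(c("treatment", "control"), n / 2))
    stratum <- sample(rep(c("high", "low"), n / 2))
    # treatment halves the hazard in the high stratum only
    lam <- ifelse(stratum == "high" & arm == "treatment", 0.05, 0.10)
    t <- rexp(n, lam)
    cox_interaction(pmin(t, 12), as.integer(t <= 12), arm, stratum)$interaction_p
  })
  expect_gt(mean(power_ps < 0.05), 0.6)

  expect_error(
    cox_interaction(c(1, 2, 3), c(1, 1, 1),
                    c("treatment", "treatment", "control"),
                    c("high", "high", "high")),
    "cells")
})

test_that("benefit confined to the high stratum gives HR < 1 there and interaction signal", {
  set.seed(27)
  n <- 2000
  arm <- sample(rep(c("treatment", "control"), n / 2))
  stratum <- sample(rep(c("high", "low"), n / 2))
  lam <- ifelse(stratum == "high" & arm == "treatment", 0.04, 0.10)
  t <- rexp(n, lam)
  times <- pmin(t, 12); events <- as.integer(t <= 12)
  hi <- stratum == "high"
  hr_high <- cox_treatment_hr(times[hi], events[hi], arm[hi])
  hr_low <- cox_treatment_hr(times[!hi], events[!hi], arm[!hi])
  expect_lt(hr_high$hazard_ratio, 1)
  expect_lt(hr_high$ci95[2], 1)
  expect_gt(hr_low$ci95[2], 1)
  ir <- cox_interaction(times, events, arm, stratum)
  expect_lt(ir$interaction_p, 0.05)
})

test_that("Schoenfeld diagnostic is calibrated and detects crossing hazards", {
  set.seed(28)
  pass <- replicate(150, {
    n <- 300
    arm <- sample(rep(c("treatment", "control"), n / 2))
    t <- rexp(n, ifelse(arm == "treatment", 0.06, 0.12))
    fit <- cox_treatment_hr(pmin(t, 12), as.integer(t <= 12), arm)
    schoenfeld_check(fit)$pass[1]
  })
  expect_gt(mean(pass), 0.88)
  expect_lt(mean(pass), 1.0)

  # strongly time-varying effect: early benefit, late harm
  reject <- replicate(40, {
    n <- 600
    arm <- sample(rep(c("treatment", "control"), n / 2))
    early <- rexp(n, ifelse(arm == "treatment", 0.02, 0.3))
    late <- rexp(n, ifelse(arm == "treatment", 0.6, 0.02))
    t <- ifelse(early < 3, early, 3 + late)
    # the gross misspecification can exhaust coxph iterations; irrelevant here
    fit <- suppressWarnings(
      cox_treatment_hr(pmin(t, 12), as.integer(t <= 12), arm))
    !schoenfeld_check(fit)$pass[1]
  })
  expect_gt(mean(reject), 0.8)

  single <- suppressWarnings(survival::coxph(
    survival::Surv(c(1, 2, 3), c(1, 0, 0)) ~ c(0, 1, 1)))
  expect_error(schoenfeld_check(single), "two events")
})

test_that("characteristics tables render counts, percentages and p-values", {
  cohort <- make_cohort(rep(c("treatment", "control"), 10),
                        rep(c(1, 0), 10),
                        x = rep(2.5, 20),
                        grp = rep(c("yes", "no"), each = 10))
  tab <- characteristics_table(cohort, cohort$data$arm)
  xrow <- tab[tab$feature == "x", ]
  expect_equal(xrow$p_value, 1)  # constant feature: identical medians
  expect_equal(xrow[[3]], xrow[[4]])

  expect_equal(format_count_pct(10, 52), "10 (19.2)")
  expect_equal(format_count_pct(26, 64), "26 (40.6)")
  expect_equal(format_count_pct(18, 72), "18 (25.0)")
  expect_equal(format_count_pct(13, 60), "13 (21.7)")

  # a strongly imbalanced binary covariate is detected
  n1 <- 116; n2 <- 132
  grp2 <- c(rep("yes", 37), rep("no", n1 - 37),
            rep("yes", 17), rep("no", n2 - 17))
  g <- c(rep("high", n1), rep("low", n2))
  cohort2 <- make_cohort(rep(c("treatment", "control"), 124),
                         rep(c(1, 0), 124), grp = grp2)
  tab2 <- characteristics_table(cohort2, g, features = "grp",
                                include_outcome = FALSE)
  expect_lt(tab2$p_value[tab2$feature == "grp"], 0.001)
  expect_equal(tab2$high[tab2$feature == "grp"], "37 (31.9)")
})
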