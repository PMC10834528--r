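test_that("the six-subject hand example matches cumulative enumeration", {
  scores <- c(0.6, 0.5, 0.4, 0.3, 0.2, 0.1)
  arms <- c("treatment", "control", "treatment", "control", "treatment",
            "control")
  successes <- c(1, 0, 0, 1, 1, 0)
  curve <- compute_qini_curve(scores, arms, successes)
  r2 <- curve[curve$rank == 2, ]
  expect_equal(r2$s_t, 1); expect_equal(r2$s_c, 0)
  expect_equal(r2$n_t, 1); expect_equal(r2$n_c, 1)
  expect_equal(r2$qini_value, 1)
  r6 <- curve[curve$rank == 6, ]
  expect_equal(r6$s_t, 2); expect_equal(r6$s_c, 1)
  expect_equal(r6$n_t, 3); expect_equal(r6$n_c, 3)
  expect_equal(r6$qini_value, 1)
  # area against the independent trapezoid oracle
  expect_equal(qini_coefficient(curve),
               oracle_qini_area(scores, arms, successes))
})

test_that("the endpoint equals the full-depth formula for any ordering", {
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(4:30, 1)
    arms <- sample(c("treatment", "control"), n, replace = TRUE)
    if (length(unique(arms)) < 2) next
    successes <- rbinom(n, 1, 0.5)
    scores <- rnorm(n)
    curve <- compute_qini_curve(scores, arms, successes)
    last <- curve[nrow(curve), ]
    expect_equal(last$qini_value,
                 sum(successes[arms == "treatment"]) -
                   sum(successes[arms == "control"]) *
                   sum(arms == "treatment") / sum(arms == "control"))
  }
})

test_that("with no control successes the curve is cumulative treated successes", {
  arms <- c("treatment", "control", "treatment", "control")
  curve <- compute_qini_curve(c(4, 3, 2, 1), arms, c(1, 0, 1, 0))
  expect_equal(curve$qini_value, curve$s_t)
})

test_that("the n_c = 0 prefix takes the s_t limit and is flagged", {
  curve <- compute_qini_curve(c(5, 4, 3, 2),
                              c("treatment", "treatment", "control", "control"),
                              c(1, 1, 1, 0))
  expect_equal(curve$qini_value[1:2], c(1, 2))
  expect_true(all(curve$control_prefix[1:2]))
  expect_false(any(curve$control_prefix[3:4]))
})

test_that("curves match the subset oracle over exhaustive small cohorts", {
  for (n in 2:5) {
    scores <- rev(seq_len(n))  # distinct, descending
    grid <- expand.grid(rep(list(c(0, 1)), 2 * n))
    for (g in seq_len(nrow(grid))) {
      bits <- as.numeric(grid[g, ])
      arms <- ifelse(bits[1:n] == 1, "treatment", "control")
      if (length(unique(arms)) < 2) next
      successes <- bits[(n + 1):(2 * n)]
      curve <- compute_qini_curve(scores, arms, successes)
      oc <- oracle_qini(scores, arms, successes)
      expect_equal(curve$qini_value, oc$qini_value)
      expect_equal(curve$diagonal_value, oc$diagonal_value)
      expect_equal(qini_coefficient(curve),
                   oracle_qini_area(scores, arms, successes))
    }
  }
})

test_that("tied scores are block-invariant", {
  scores <- c(0.5, 0.3, 0.3, 0.3, 0.1, 0.1)
  arms <- c("treatment", "control", "treatment", "treatment", "control",
            "control")
  successes <- c(1, 1, 0, 1, 0, 1)
  curve <- compute_qini_curve(scores, arms, successes)
  expect_equal(curve$rank, c(1, 4, 6))  # block boundaries only
  perm <- c(1, 4, 3, 2, 6, 5)  # permute within tie blocks
  curve2 <- compute_qini_curve(scores[perm], arms[perm], successes[perm])
  expect_equal(as.data.frame(curve), as.data.frame(curve2))
})

test_that("curve, coefficient and cutoff are rank-based", {
  set.seed(11)
  scores <- rnorm(40)
  arms <- rep(c("treatment", "control"), 20)
  successes <- rbinom(40, 1, 0.5)
  a <- compute_qini_curve(scores, arms, successes)
  b <- compute_qini_curve(exp(3 * scores), arms, successes)
  expect_equal(a$qini_value, b$qini_value)
  expect_equal(a$rank, b$rank)
  expect_equal(qini_coefficient(a), qini_coefficient(b))
  ca <- select_optimal_cutoff(a)
  cb <- select_optimal_cutoff(b)
  expect_equal(attr(ca, "rank"), attr(cb, "rank"))
})

test_that("random scorings have near-zero expected coefficient", {
  set.seed(12)
  arms <- rep(c("treatment", "control"), 50)
  successes <- rbinom(100, 1, 0.4)
  coefs <- replicate(300, {
    qini_coefficient(compute_qini_curve(rnorm(100), arms, successes))
  })
  # mean area scales with n; normalize by n for the tolerance
  expect_lt(abs(mean(coefs)) / 100, 0.05)
})

test_that("cutoff selection maximizes the lead over the diagonal", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  arms <- c("treatment", "control", "treatment", "control", "treatment",
            "control")
  successes <- c(1, 0, 1, 0, 0, 1)
  curve <- compute_qini_curve(scores, arms, successes)
  lead <- curve$qini_value - curve$diagonal_value
  cut <- select_optimal_cutoff(curve)
  k <- which.max(lead)
  expect_equal(as.numeric(cut), curve$threshold_phi[k])
  expect_false(attr(cut, "no_benefit"))

  # a single tie block: the curve cannot beat its own chord
  flat <- compute_qini_curve(rep(0.2, 6), arms, successes)
  cut2 <- select_optimal_cutoff(flat)
  expect_true(attr(cut2, "no_benefit"))
  expect_equal(as.numeric(cut2), Inf)
})

test_that("subjects above the selected cutoff are enriched for true benefit", {
  g <- generate_cohort(synthetic_config(n = 4000, seed = 15,
                                        missingness_rates = numeric(0)))
  halves <- split_by_registration_order(g$cohort)
  rec <- fit_preprocess_recipe(halves$first)
  m <- fit_uplift_model(halves$first, "logistic_regression", rec, seed = 2)
  sc <- uplift_scores(m, halves$second)
  curve <- compute_qini_curve(sc$uplift_score, halves$second$data$arm,
                              halves$second$data$success)
  cut <- select_optimal_cutoff(curve)
  truth <- g$truth$true_uplift[match(sc$subject_id, g$truth$subject_id)]
  high <- sc$uplift_score >= as.numeric(cut)
  expect_gt(mean(truth[high] > 0), mean(truth[!high] > 0))
})

test_that("model selection prefers the oracle scorer and breaks ties deterministically", {
  g <- generate_cohort(synthetic_config(n = 2000, seed = 16,
                                        missingness_rates = numeric(0)))
  d <- g$cohort$data
  set.seed(17)
  oracle <- qini_summary(g$truth$true_uplift, d$arm, d$success, "oracle")
  random <- qini_summary(rnorm(2000), d$arm, d$success, "random")
  expect_equal(select_best_model(list(random, oracle)), "oracle")
  expect_gt(oracle$qini_coefficient, random$qini_coefficient)

  expect_equal(select_best_model(list(oracle)), "oracle")
  expect_error(select_best_model(list()), "no candidate")

  # registry-order tie-break on identical coefficients
  s1 <- oracle; s1$classifier_id <- "random_forest"
  s2 <- oracle; s2$classifier_id <- "decision_tree"
  reg <- available_classifiers()$id
  first <- intersect(reg, c("random_forest", "decision_tree"))[1]
  expect_equal(select_best_model(list(s1, s2)), first)
})
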