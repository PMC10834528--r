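test_that("missingness screening uses a strict threshold", {
  scr <- screen_missingness(make_missing_cohort(16), threshold = 0.15)
  expect_true("x" %in% scr$dropped)
  scr <- screen_missingness(make_missing_cohort(15), threshold = 0.15)
  expect_true("x" %in% scr$kept)
  scr <- screen_missingness(make_missing_cohort(0), threshold = 0.15)
  expect_true(all(c("x", "grp") %in% scr$kept))
})

test_that("imputation uses training statistics and the constant level", {
  train <- make_cohort(c("treatment", "control", "treatment"), c(1, 0, 1),
                       x = c(1, 2, NA), grp = c("A", NA, "B"))
  iv <- fit_impute(train)
  expect_equal(iv$x, 1.5)
  expect_equal(iv$grp, "not available")
  imp <- apply_impute(iv, train)
  expect_equal(imp$data$x, c(1, 2, 1.5))
  expect_equal(imp$data$grp, c("A", "not available", "B"))
  expect_false(anyNA(covariate_data(imp)))

  # a held-out row is imputed with the training, not its own, mean
  test <- make_cohort(c("treatment", "control"), c(1, 0),
                      x = c(100, NA))
  expect_equal(apply_impute(iv, test)$data$x, c(100, 1.5))

  all_missing <- make_cohort("treatment", 1, x = NA)
  expect_error(fit_impute(all_missing), "no observed")
})

test_that("correlation pruning keeps one feature per correlated group", {
  set.seed(1)
  x <- rnorm(50)
  dup <- make_multi_cohort(list(a = x, b = x, c = rnorm(50)))
  pr <- prune_correlated(dup, 0.7, keep_priority = c("b", "a"))
  expect_setequal(pr$kept, c("b", "c"))
  expect_equal(pr$dropped$dropped, "a")
  expect_equal(pr$dropped$r, 1)

  # |r| = 0.69 is below the strict threshold: both kept
  y <- 0.69 * scale(x)[, 1] + sqrt(1 - 0.69^2) * scale(rnorm(50))[, 1]
  resid <- residuals(lm(y ~ x))
  y_exact <- 0.69 * scale(x)[, 1] +
    sqrt(1 - 0.69^2) * scale(resid)[, 1]
  near <- make_multi_cohort(list(a = scale(x)[, 1], b = y_exact))
  r_ab <- cor(near$data$a, near$data$b)
  expect_equal(abs(r_ab), 0.69, tolerance = 1e-10)
  pr <- prune_correlated(near, 0.7, keep_priority = c("a"))
  expect_setequal(pr$kept, c("a", "b"))

  expect_error(prune_correlated(dup, 0.7), "keep_priority")
})

test_that("a mutually correlated triple collapses to the top priority", {
  set.seed(2)
  base <- rnorm(200)
  trio <- make_multi_cohort(list(
    a = base + rnorm(200, sd = 0.1),
    b = base + rnorm(200, sd = 0.1),
    c = base + rnorm(200, sd = 0.1),
    d = rnorm(200)))
  cm <- cor(as.matrix(trio$data[c("a", "b", "c")]))
  expect_true(all(abs(cm[upper.tri(cm)]) > 0.7))  # premise of the check
  pr <- prune_correlated(trio, 0.7, keep_priority = c("c", "a", "b"))
  expect_setequal(pr$kept, c("c", "d"))
  # brute-force connected component over the |r| > 0.7 graph agrees
  adj <- abs(cor(as.matrix(trio$data[c("a", "b", "c", "d")]))) > 0.7
  expect_equal(sum(adj["d", c("a", "b", "c")]), 0)
})

test_that("IQR scaling matches the quartile convention", {
  cohort <- make_multi_cohort(list(v = c(1, 2, 3, 4, 5)))
  sp <- fit_scale(cohort)
  expect_equal(unname(sp$v["center"]), 3)
  expect_equal(unname(sp$v["spread"]), 2)
  scaled <- apply_scale(sp, cohort)
  expect_equal(scaled$data$v, c(-1, -0.5, 0, 0.5, 1))

  const <- make_multi_cohort(list(v = rep(4, 6)))
  expect_warning(spc <- fit_scale(const), "zero interquartile")
  expect_equal(suppressWarnings(apply_scale(spc, const)$data$v), rep(0, 6))

  set.seed(3)
  big <- make_multi_cohort(list(v = rnorm(101, 10, 3)))
  scaled <- apply_scale(fit_scale(big), big)
  expect_equal(median(scaled$data$v), 0)
  expect_equal(unname(diff(quantile(scaled$data$v, c(0.25, 0.75), type = 7))),
               1)
})

test_that("the fitted recipe is a pure function of training data", {
  set.seed(4)
  g <- generate_cohort(synthetic_config(n = 300, seed = 17))
  halves <- split_by_registration_order(g$cohort)
  recipe <- fit_preprocess_recipe(halves$first)

  out1 <- apply_recipe(recipe, halves$second)
  out2 <- apply_recipe(recipe, halves$second)
  expect_identical(out1$data, out2$data)
  expect_false(anyNA(covariate_data(out1)))

  # training statistics, not test statistics: the imputed value in the test
  # half equals the training mean
  f <- "brain_natriuretic_peptide"
  train_mean <- mean(halves$first$data[[f]], na.rm = TRUE)
  expect_equal(recipe$impute_values[[f]], train_mean)
  miss <- is.na(halves$second$data[[f]])
  if (any(miss)) {
    imputed_scaled <- out1$data[[f]][miss]
    p <- recipe$scale_params[[f]]
    expect_true(all(abs(imputed_scaled -
                          (train_mean - p[["center"]]) / p[["spread"]]) < 1e-12))
  }
})
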