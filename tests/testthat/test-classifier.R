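# AUC, Mann-Whitney comparison, BCa bootstrap, nested CV and model application.

test_that("auc matches the pair-enumeration oracle and pROC", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(1, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auc(1:4, rep(1, 4)), "both classes")

  set.seed(61)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    s <- sample(1:6, n, replace = TRUE) # ties on purpose
    l <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auc(s, l), oracle_auc(s, l == 1))
  }

  s <- c(0.1, 0.4, 0.35, 0.8, 0.7, 0.2)
  l <- c(0, 0, 1, 1, 1, 0)
  expect_equal(auc(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("compare_auc reproduces exact enumeration for small samples", {
  res <- compare_auc(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 0.1) # 2/20 of the C(6,3) rank assignments
  expect_equal(res$method, "exact")

  set.seed(62)
  for (i in 1:10) {
    a <- round(stats::rnorm(4), 3)
    b <- round(stats::rnorm(5, 0.5), 3)
    if (anyDuplicated(c(a, b))) next
    expect_equal(compare_auc(a, b)$p_value, oracle_mann_whitney_p(a, b))
  }

  expect_equal(compare_auc(c(1, 2, 3), c(4, 5, 6))$p_value,
               compare_auc(c(4, 5, 6), c(1, 2, 3))$p_value)
  same <- compare_auc(rep(0.7, 30), rep(0.7, 30))
  expect_gt(same$p_value, 0.9) # no location shift
  expect_equal(same$method, "degenerate")
})

test_that("bca_ci behaves on degenerate, symmetric and skewed samples", {
  const <- bca_ci(rep(0.5, 10))
  expect_equal(const$lower, 0.5)
  expect_equal(const$upper, 0.5)

  # zero jackknife skewness: BCa ~ percentile bootstrap
  x <- seq(-1, 1, length.out = 40)
  ci <- bca_ci(x, level = 0.95, B = 4000, seed = 2)
  set.seed(2)
  perc <- stats::quantile(
    replicate(4000, mean(sample(x, replace = TRUE))), c(0.025, 0.975)
  )
  expect_lt(abs(ci$lower - perc[[1]]), 0.03)
  expect_lt(abs(ci$upper - perc[[2]]), 0.03)
  expect_lte(ci$lower, ci$estimate)
  expect_gte(ci$upper, ci$estimate)

  # skewed sample: agree with the boot package's BCa within Monte-Carlo error
  set.seed(63)
  y <- stats::rexp(40)
  ci2 <- bca_ci(y, level = 0.95, B = 5000, seed = 3)
  bref <- boot::boot.ci(
    boot::boot(y, function(d, i) mean(d[i]), R = 5000),
    type = "bca", conf = 0.95
  )$bca
  expect_lt(abs(ci2$lower - bref[4]), 0.06)
  expect_lt(abs(ci2$upper - bref[5]), 0.06)
})

test_that("nested_cv is deterministic, leakage-free and importance-normalised", {
  coh <- suppressWarnings(generate_cohort(
    60, outcome_spec = outcome_model_spec(intercept = -2,
                                          coefficients = c("SDH:Parietal Lobe" = 2)),
    seed = 64, shape = c(32, 32, 32), keep_volumes = FALSE
  ))
  ft <- build_feature_table(coh, exp = "Exp6")
  cfg <- cv_config(outer_folds = 3, outer_repeats = 2, inner_folds = 3,
                   search_budget = 3, seed = 9)
  r1 <- nested_cv(ft, config = cfg)
  r2 <- nested_cv(ft, config = cfg)
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$importance, r2$importance)
  expect_equal(length(r1$auc) + r1$skipped, 6)
  expect_true(all(r1$auc >= 0 & r1$auc <= 1))
  expect_true(all(r1$importance >= 0))
  expect_equal(sum(r1$importance), 1)
  expect_equal(nrow(tidy(r1)), length(r1$auc))
  expect_equal(glance(r1)$mean_auc, mean(r1$auc))

  # model application: accuracy equals the brute-force confusion count
  ev <- apply_model(r1, ft)
  pred <- attr(ev, "predictions")
  expect_equal(ev$correct, sum(pred$predicted == pred$observed))
  expect_equal(ev$accuracy, ev$correct / ev$total)
  expect_equal(ev$fraction, sprintf("%d/%d", ev$correct, ev$total))

  # refit comfortably beats chance on its own training data (the outcome
  # itself is stochastic, so perfect separation is not attainable)
  expect_gt(ev$accuracy, 0.7)

  # feature mismatch is a named error
  ft_bad <- ft
  names(ft_bad)[3] <- "bogus"
  expect_error(apply_model(r1, ft_bad), "training manifest")
})

test_that("run_experiments assembles the variants x experiments grid", {
  coh <- suppressWarnings(generate_cohort(
    40, outcome_spec = outcome_model_spec(intercept = 0),
    seed = 65, shape = c(32, 32, 32), keep_volumes = FALSE
  ))
  cfg <- cv_config(outer_folds = 3, outer_repeats = 1, inner_folds = 2,
                   search_budget = 2, seed = 1)
  grid <- run_experiments(
    coh,
    variants = list(seven = list(quant_col = "quant", scheme = "seven"),
                    four = list(quant_col = "quant", scheme = "four")),
    experiments = c(3, 7), config = cfg
  )
  expect_equal(nrow(grid), 4)
  expect_true(all(c("mean_auc", "sd_auc", "result") %in% names(grid)))
  comps <- attr(grid, "comparisons")
  expect_equal(nrow(comps), 1)
  expect_true(comps$p_value >= 0 && comps$p_value <= 1)
  expect_equal(nrow(tidy(grid)), 4)
})
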