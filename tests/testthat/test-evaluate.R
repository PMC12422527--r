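test_that("stratified folds partition indices with balanced classes", {
  labels <- rep(c(0, 1), 5)
  folds <- stratified_kfold(labels, 5, seed = 2)
  expect_length(folds, 5)
  expect_equal(sort(unlist(folds)), 1:10)
  for (f in folds) {
    expect_length(f, 2)
    expect_equal(sum(labels[f]), 1)
  }
  expect_identical(folds, stratified_kfold(labels, 5, seed = 2))
  expect_error(stratified_kfold(c(1, 0, 0, 0), 2, seed = 1), "at least k")

  set.seed(7)
  y <- rbinom(103, 1, 0.3)
  folds <- stratified_kfold(y, 5, seed = 9)
  expect_equal(sort(unlist(folds)), seq_along(y))
  pos_per_fold <- vapply(folds, function(f) sum(y[f]), numeric(1))
  expect_lte(diff(range(pos_per_fold)), 1)
})

test_that("AUROC matches hand cases and the pair-counting oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.9, 0.6, 0.4, 0.1), c(1, 0, 1, 0)), 0.75)

  set.seed(3)
  for (i in 1:6) {
    n <- sample(20:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # ties likely
    expect_equal(auroc(s, y), auroc_oracle(s, y), tolerance = 1e-12)
    expect_equal(auroc(s, 1 - y), 1 - auroc(s, y), tolerance = 1e-12)
  }
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("sensitivity threshold is the largest satisfying the constraint", {
  expect_equal(sensitivity_threshold(c(0.9, 0.2, 0.8, 0.1),
                                     c(1, 1, 0, 0), 0.5), 0.2)
  ## all positives share the maximum score
  expect_equal(sensitivity_threshold(c(0.9, 0.9, 0.5, 0.2),
                                     c(1, 1, 0, 0), 0.5), 0.9)
  ## min_sens 0: any threshold with at least one captured positive works,
  ## so the largest candidate wins
  expect_equal(sensitivity_threshold(c(0.9, 0.3, 0.2), c(1, 1, 0), 0), 0.9)
  ## unattainable constraint falls back to the minimum score
  expect_equal(sensitivity_threshold(c(0.5, 0.4), c(0, 1), 0.99), 0.4)

  ## contract property under exhaustive scan of the candidate set
  set.seed(13)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    y <- rbinom(n, 1, 0.5); if (sum(y) == 0) y[1] <- 1
    s <- round(runif(n), 2)
    t <- sensitivity_threshold(s, y, 0.5)
    sens <- function(th) mean(s[y == 1] >= th)
    if (sens(t) > 0.5) {
      larger <- unique(s[s > t])
      expect_true(all(vapply(larger, sens, numeric(1)) <= 0.5))
    } else {
      expect_equal(t, min(s))
    }
  }
})

test_that("classification metrics are support-weighted; recall equals accuracy", {
  m <- classification_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(m), c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  m2 <- classification_metrics(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$precision, 0.5)
  expect_equal(m2$f1, 0.5)

  set.seed(21)
  for (i in 1:8) {
    n <- sample(5:50, 1)
    pred <- rbinom(n, 1, 0.5); lab <- rbinom(n, 1, 0.4)
    mm <- classification_metrics(pred, lab)
    expect_equal(mm$recall, mm$accuracy, tolerance = 1e-12)
  }
  expect_error(classification_metrics(integer(0), integer(0)))
})

test_that("subgroup report covers partitions and degenerate rules", {
  tab <- small_signal_cohort(n = 500, seed = 71)
  fit <- quick_fit(cohort_slice(tab, 1:380))
  test <- cohort_slice(tab, 381:500)
  y <- outcome_values(test)

  full_and_split <- list(rule(),
                         rule(c(peritonitis = TRUE)),
                         rule(c(peritonitis = FALSE)))
  rep <- subgroup_report(fit, test, rules = full_and_split, threshold = 0.5)
  expect_equal(rep$metrics$n[1], nrow(test))
  expect_equal(rep$metrics$n[2] + rep$metrics$n[3], nrow(test))

  ## whole-test rule metrics equal global metrics
  pred <- (predict(fit, test, type = "risk") >= 0.5) * 1
  glob <- classification_metrics(pred, y)
  expect_equal(rep$metrics$accuracy[1], glob$accuracy)
  expect_equal(rep$metrics$f1[1], glob$f1)

  ## rule covering nothing yields n = 0 and absent metrics
  never <- rule(c(peritonitis = TRUE, hepatic_encephalopathy = TRUE,
                  abdominal_fluid = TRUE))
  df <- as.data.frame(unclass(test))
  if (length(rule_coverage(never, test)) == 0) {
    rep0 <- subgroup_report(fit, test, rules = list(never))
    expect_equal(rep0$metrics$n, 0)
    expect_true(is.na(rep0$metrics$accuracy))
  }

  ## histogram counts selected bases
  h <- rep$selection_histogram[[1]]
  expect_length(h, length(fit$pool$bases))
  expect_gte(sum(h), nrow(test))
})

test_that("run_experiment produces a reproducible per-fold report", {
  tab <- small_signal_cohort(n = 420, seed = 81)
  config <- list(cohort = tab, k_folds = 2, seed = 3,
                 fit_args = list(families = c("logistic_regression", "lda"),
                                 min_per_class = 10))
  r1 <- suppressWarnings(run_experiment(config))
  expect_s3_class(r1, "cades_cv")
  expect_equal(sort(unique(r1$per_fold$fold)), 1:2)
  expect_equal(nrow(r1$per_fold), 2 * (1 + 2))   # cades + 2 baselines per fold
  expect_true(all(r1$per_fold$auroc >= 0 & r1$per_fold$auroc <= 1, na.rm = TRUE))
  agg <- r1$aggregate
  expect_true(all(agg$auroc_min <= agg$auroc_mean + 1e-12 &
                  agg$auroc_mean <= agg$auroc_max + 1e-12))

  r2 <- suppressWarnings(run_experiment(config))
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$aggregate, r2$aggregate)
  expect_output(print(r1), "Cross-validated")
})

test_that("fitted artifacts never depend on held-out data", {
  tab <- small_signal_cohort(n = 400, seed = 91)
  train <- cohort_slice(tab, 1:300)
  fit <- quick_fit(train, seed = 5)

  test_a <- cohort_slice(tab, 301:400)
  ## a wildly perturbed test set must see the identical fitted model:
  ## same screen, rules, pool predictions, and identical per-row predictions
  df <- as.data.frame(unclass(test_a))
  df$albumin <- df$albumin + 1000
  test_b <- cohort_table(df, column_roles(test_a))

  fit2 <- quick_fit(train, seed = 5)
  expect_identical(fit$screen, fit2$screen)
  expect_identical(lapply(fit$rules, format), lapply(fit2$rules, format))

  ## prediction of one row does not depend on the other rows in newdata
  p_all <- predict(fit, test_a, type = "risk")
  p_one <- predict(fit, cohort_slice(test_a, 7), type = "risk")
  expect_equal(p_all[7], p_one, tolerance = 1e-12)
})
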