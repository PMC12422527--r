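test_that("feature-space regions are exact nearest neighbors with index ties", {
  dsel <- toy_cohort(lab1 = c(0, 1, 2, 3, 10, 11, 12, 13),
                     lab2 = c(0, 0, 0, 0, 0, 0, 0, 0))
  q <- cohort_slice(dsel, 3)
  r <- region_feature(q, dsel, K = 1, feature_names = c("lab1", "lab2"))
  expect_equal(r$members, 3)
  expect_equal(r$distances, 0)

  r_all <- region_feature(q, dsel, K = 8, feature_names = c("lab1", "lab2"))
  expect_setequal(r_all$members, 1:8)

  ## hand-checked 2-D case: query (2.5, 0) -> rows 3 and 4 nearest
  r2 <- region_feature(c(lab1 = 2.5, lab2 = 0), dsel, K = 2,
                       feature_names = c("lab1", "lab2"))
  expect_setequal(r2$members, c(3, 4))

  ## exact distance ties resolve to the lower row index
  dsel2 <- toy_cohort(lab1 = c(5, 5, 5, 5, 0, 0, 0, 0))
  r3 <- region_feature(c(lab1 = 5, lab2 = 4.5), dsel2, K = 2,
                       feature_names = "lab1")
  expect_equal(r3$members, c(1, 2))
})

test_that("diagnosis-space regions are Hamming-nearest and class-balanced", {
  dsel <- cohort_table(
    data.frame(A = c(1, 1, 0, 1), B = c(0, 1, 0, 0),
               lab = c(1, 2, 3, 4), readmitted = c(1, 1, 0, 0)),
    c(A = "diagnosis", B = "diagnosis", lab = "lab_admission",
      readmitted = "outcome"))
  r <- region_diagnosis(c(A = 1, B = 0), dsel, K_prime = 2)
  expect_equal(sort(r$members), c(1, 4))          # Hamming 0 in each class
  expect_equal(r$distances, c(0, 0))

  r4 <- region_diagnosis(c(A = 1, B = 0), dsel, K_prime = 4)
  y <- outcome_values(dsel)
  expect_equal(sum(y[r4$members] == 1), 2)
  expect_equal(sum(y[r4$members] == 0), 2)

  one_class <- cohort_slice(dsel, 1:2)
  expect_error(region_diagnosis(c(A = 1, B = 0), one_class, K_prime = 2),
               "each outcome class")
})

test_that("meta-features of a perfect and a constant classifier are pinned", {
  set.seed(33)
  n <- 40
  y <- rep(c(0, 1), n / 2)
  dsel <- cohort_table(
    data.frame(D = rbinom(n, 1, 0.5), lab1 = y * 8 + rnorm(n),
               lab2 = rnorm(n), readmitted = y),
    c(D = "diagnosis", lab1 = "lab_admission", lab2 = "lab_admission",
      readmitted = "outcome"))
  ## near-perfect base: separable logistic
  pool <- train_pool(
    cohort_table(data.frame(D = rbinom(40, 1, 0.5),
                            lab1 = rep(c(0, 8), 20) + rnorm(40),
                            lab2 = rnorm(40),
                            readmitted = rep(c(0, 1), 20)),
                 column_roles(dsel)),
    list(list(rule = rule(), family = "logistic_regression")),
    feature_fraction = 1, undersample = FALSE, seed = 2)
  mf <- extract_meta_features(pool, 1, cohort_slice(dsel, 5), dsel,
                              K = 7, Kp = 5, K_prime = 10)
  expect_equal(mf$f1, rep(1, 7))
  expect_equal(mf$f3, 1)
  expect_equal(mf$f4, rep(1, 5))
  expect_equal(mf$f6, 1)
  expect_length(mf$v, 2 * 7 + 5 + 3)
  expect_true(all(mf$v >= 0 & mf$v <= 1))
  expect_equal(mf$f3, mean(mf$f1))

  ## constant classifier: balanced theta-prime forces f6 = 0.5 exactly
  cp <- constant_pool(c("D", "lab1", "lab2"))
  mfc <- extract_meta_features(cp, 1, cohort_slice(dsel, 5), dsel,
                               K = 7, Kp = 5, K_prime = 10)
  expect_equal(mfc$f6, 0.5)
  expect_equal(mfc$f5, 0.5)
  expect_equal(mfc$f3, mean(mfc$f1))
})

test_that("meta-dataset has one labeled row per classifier-instance pair", {
  tab <- small_signal_cohort(n = 260, seed = 41)
  dsel <- cohort_slice(tab, 1:60)
  train <- cohort_slice(tab, 61:260)
  pool <- train_pool(train,
                     list(list(rule = rule(), family = "lda"),
                          list(rule = rule(), family = "naive_bayes")),
                     seed = 3)
  md <- build_meta_dataset(pool, dsel, K = 5, Kp = 3, K_prime = 6)
  expect_equal(nrow(md), 2 * 60)
  expect_true(all(md$alpha %in% c(0, 1)))
  vcols <- setdiff(names(md), c("classifier_index", "instance_index", "alpha"))
  expect_length(vcols, 2 * 5 + 3 + 3)
  expect_true(all(as.matrix(md[vcols]) >= 0 & as.matrix(md[vcols]) <= 1))
  expect_equal(md$f3, rowMeans(md[paste0("f1_", 1:5)]), tolerance = 1e-12)

  ## mean(alpha) per classifier equals that classifier's DSEL accuracy
  P <- output_profile(pool, dsel)
  acc <- colMeans((P >= 0.5) == outcome_values(dsel))
  expect_equal(as.numeric(tapply(md$alpha, md$classifier_index, mean)),
               as.numeric(acc), tolerance = 1e-12)

  ## constant-positive classifier: alphas equal the true labels
  cp <- constant_pool(pool$feature_names)
  mdc <- build_meta_dataset(cp, dsel, K = 5, Kp = 3, K_prime = 6)
  expect_equal(mdc$alpha, outcome_values(dsel))
})

test_that("meta-classifier learns a separable competence rule", {
  tab <- small_signal_cohort(n = 400, seed = 51)
  dsel <- cohort_slice(tab, 1:100)
  pool <- train_pool(cohort_slice(tab, 101:400),
                     list(list(rule = rule(), family = "logistic_regression"),
                          list(rule = rule(), family = "qda")),
                     seed = 4)
  md <- build_meta_dataset(pool, dsel)
  md$alpha <- as.numeric(md$f3 > 0.5)   # separable by construction
  expect_error(train_meta(md[md$alpha == 1, ]), "both alpha")
  lam <- train_meta(md, family = "logistic_regression", seed = 6)
  vcols <- setdiff(names(md), c("classifier_index", "instance_index", "alpha"))
  p <- predict_meta(lam, as.matrix(md[vcols]))
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(mean((p >= 0.5) == md$alpha), 0.95)

  lam2 <- train_meta(md, family = "logistic_regression", seed = 6)
  expect_equal(predict_meta(lam2, as.matrix(md[vcols])), p, tolerance = 1e-12)
})

test_that("identical bases receive identical competence scores", {
  tab <- small_signal_cohort(n = 300, seed = 61)
  dsel <- cohort_slice(tab, 1:80)
  train <- cohort_slice(tab, 81:300)
  pool <- train_pool(train,
                     list(list(rule = rule(), family = "lda"),
                          list(rule = rule(), family = "lda"),
                          list(rule = rule(), family = "naive_bayes")),
                     feature_fraction = 1, undersample = FALSE, seed = 7)
  md <- build_meta_dataset(pool, dsel)
  lam <- train_meta(md, seed = 8)
  x <- cohort_slice(tab, 150)
  sc <- score_competences(lam, pool, x, dsel)
  expect_length(sc, 3)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(sc[1], sc[2], tolerance = 1e-12)   # duplicated base
})

test_that("selection follows the argmax-set / majority-vote contract", {
  ## three bases with controlled votes on a probe point: lab1 high =>
  ## base 1 and 2 vote positive, base 3 (label-flipped training) votes 0
  tab <- separable_cohort(n = 60, seed = 71)
  flipped <- cohort_table(
    within(as.data.frame(unclass(tab)), readmitted <- 1 - readmitted),
    column_roles(tab))
  b1 <- train_pool(tab, list(list(rule = rule(), family = "logistic_regression")),
                   undersample = FALSE, seed = 1)$bases[[1]]
  b2 <- train_pool(tab, list(list(rule = rule(), family = "lda")),
                   undersample = FALSE, seed = 2)$bases[[1]]
  b3 <- train_pool(flipped, list(list(rule = rule(), family = "logistic_regression")),
                   undersample = FALSE, seed = 3)$bases[[1]]
  pool <- structure(list(bases = list(b1, b2, b3),
                         feature_names = predictor_cols(tab)),
                    class = "cades_pool")
  x <- cohort_slice(tab, which(outcome_values(tab) == 1)[1])  # positive point

  s <- select_and_predict(c(0.9, 0.9, 0.2), pool, x)
  expect_equal(sort(s$selected_indices), c(1, 2))
  expect_equal(s$predicted_label, 1)

  s2 <- select_and_predict(c(0.4, 0.4, 0.4), pool, x)   # all equal: full vote
  expect_equal(sort(s2$selected_indices), 1:3)
  expect_equal(s2$predicted_label, 1)                   # votes (1,1,0)

  ## vote flips when two of three selected bases vote negative
  s3 <- select_and_predict(c(0.2, 0.4, 0.4), pool, x)
  expect_equal(sort(s3$selected_indices), c(2, 3))
  ## tie between one 1-vote and one 0-vote: mean posterior decides
  expect_equal(s3$predicted_label,
               as.numeric(s3$risk_score > 0.5 ||
                          (s3$risk_score == 0.5)))

  ## single-member pool degeneracy
  lone <- structure(list(bases = list(b1),
                         feature_names = predictor_cols(tab)),
                    class = "cades_pool")
  s4 <- select_and_predict(0.7, lone, x)
  p1 <- unname(output_profile(lone, x)[1, 1])
  expect_equal(s4$risk_score, p1)
  expect_equal(s4$predicted_label, as.numeric(p1 >= 0.5))
})
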