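test_that("Mann-Whitney U matches hand-derived exact cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)  # 2 * 1/choose(6,3)

  ## same multiset in both groups -> p = 1 by symmetry
  expect_equal(mann_whitney_u(c(2, 5, 5, 9), c(2, 5, 5, 9))$p_value, 1)
})

test_that("Mann-Whitney exact p agrees with enumeration oracle under ties", {
  set.seed(11)
  for (i in 1:12) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(1:4, nx, replace = TRUE)  # heavy ties
    y <- sample(1:4, ny, replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$p_value, mw_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U complementarity and tie-free agreement with wilcox.test", {
  set.seed(4)
  for (i in 1:8) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    ux <- mann_whitney_u(x, y)$U
    uy <- mann_whitney_u(y, x)$U
    expect_equal(ux + uy, length(x) * length(y))
    expect_equal(mann_whitney_u(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  ## large-sample normal branch against wilcox.test without continuity corr.
  set.seed(5)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  expect_equal(mann_whitney_u(x, y)$p_value,
               wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-10)
  expect_error(mann_whitney_u(numeric(0), 1))
})

test_that("two_by_two_test picks the documented branch with correct values", {
  r <- two_by_two_test(5, 5, 5, 5)
  expect_equal(r$test, "chi_square")
  expect_equal(r$p_value, 1)

  r <- two_by_two_test(10, 0, 0, 10)
  expect_equal(r$test, "fisher_exact")
  expect_equal(r$p_value, 2 / choose(20, 10), tolerance = 1e-12)

  r <- two_by_two_test(30, 70, 70, 30)
  expect_equal(r$test, "chi_square")
  expect_equal(r$statistic, sum((abs(c(30, 70, 70, 30) - 50) - 0.5)^2 / 50),
               tolerance = 1e-12)

  ## zero margin short-circuits to Fisher with p = 1
  r <- two_by_two_test(0, 0, 5, 5)
  expect_equal(r$test, "fisher_exact")
  expect_equal(r$p_value, 1)
})

test_that("missingness filter drops strictly-exceeding rows only", {
  df <- as.data.frame(matrix(1, nrow = 3, ncol = 10))
  names(df) <- paste0("lab", 1:10)
  df$lab1[2] <- NA; df$lab2[2] <- NA       # 2/10 missing
  df$lab1[3] <- NA                          # 1/10 missing
  df$readmitted <- c(1, 0, 1)
  tab <- cohort_table(df, c(setNames(rep("lab_admission", 10), paste0("lab", 1:10)),
                            readmitted = "outcome"))
  out <- filter_patients_by_missingness(tab, 0.10)
  expect_equal(nrow(out), 2)                # row 2 dropped, row 3 kept
  expect_equal(out$lab3, c(1, 1))

  complete <- cohort_slice(tab, 1)
  expect_identical(unclass(filter_patients_by_missingness(complete, 0))$lab1,
                   unclass(complete)$lab1)
  expect_warning(filter_patients_by_missingness(
    inject_missingness(tab, c(lab3 = 1), seed = 1), 0))
})

test_that("knn imputation reproduces hand-computed neighbors", {
  tab <- cohort_table(
    data.frame(lab1 = c(1, 3, 2), lab2 = c(2, 4, NA), readmitted = c(0, 1, 0)),
    c(lab1 = "lab_admission", lab2 = "lab_admission", readmitted = "outcome"))
  out <- knn_impute(tab, k = 2)
  expect_equal(out$lab2[3], 3)             # mean(2, 4)
  expect_false(anyNA(as.data.frame(unclass(out))))

  ## zero-distance duplicate row dominates at k = 1
  tab2 <- cohort_table(
    data.frame(lab1 = c(5, 5, 1), lab2 = c(7, NA, 0), readmitted = c(0, 1, 0)),
    c(lab1 = "lab_admission", lab2 = "lab_admission", readmitted = "outcome"))
  expect_equal(knn_impute(tab2, k = 1)$lab2[2], 7)

  ## identity on complete tables; idempotence on own output
  expect_identical(knn_impute(out, k = 2), out)

  ## fully-missing column is rejected by name
  tab3 <- inject_missingness(tab, c(lab1 = 1), seed = 3)
  expect_error(knn_impute(tab3, k = 1), "lab1")
})

test_that("knn imputation with external donors uses donor values only", {
  donors <- cohort_table(
    data.frame(lab1 = c(0, 0, 10), lab2 = c(1, 3, 100), readmitted = c(0, 1, 0)),
    c(lab1 = "lab_admission", lab2 = "lab_admission", readmitted = "outcome"))
  target <- cohort_table(
    data.frame(lab1 = 0, lab2 = NA, readmitted = 0),
    c(lab1 = "lab_admission", lab2 = "lab_admission", readmitted = "outcome"))
  out <- knn_impute(target, k = 2, donors = donors)
  expect_equal(out$lab2[1], 2)             # mean of the two lab1=0 donors
})

test_that("binary cells impute to the neighbor mode with ties to 0", {
  df <- data.frame(D = c(1, 1, 0, 0, NA), lab = c(1, 1.1, 1.05, 0.95, 1),
                   readmitted = c(1, 0, 1, 0, 1))
  tab <- cohort_table(df, c(D = "diagnosis", lab = "lab_admission",
                            readmitted = "outcome"))
  out <- knn_impute(tab, k = 4)            # neighbors split 2/2 -> tie -> 0
  expect_equal(out$D[5], 0)
})

test_that("univariate screening selects associated variables, never constants", {
  set.seed(9)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  tab <- cohort_table(
    data.frame(same = y,                       # perfect association
               const = 1,                      # constant
               noise = rbinom(n, 1, 0.5),
               lab_signal = rnorm(n, mean = 2 * y),
               lab_const = 5,
               readmitted = y),
    c(same = "diagnosis", const = "diagnosis", noise = "diagnosis",
      lab_signal = "lab_admission", lab_const = "lab_admission",
      readmitted = "outcome"))
  res <- univariate_screen(tab, alpha = 0.05)
  expect_equal(nrow(res), 5)
  expect_true(res$selected[res$variable == "same"])
  expect_true(res$selected[res$variable == "lab_signal"])
  expect_false(res$selected[res$variable == "const"])
  expect_false(res$selected[res$variable == "lab_const"])
  expect_equal(res$p_value[res$variable == "const"], 1)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))

  ## permutation equivariance: shuffling rows leaves every p-value unchanged
  perm <- sample(n)
  res2 <- univariate_screen(cohort_slice(tab, perm), alpha = 0.05)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-12)
})

test_that("MELD matches the printed formula with UNOS flooring", {
  expect_equal(compute_meld(1, 1, 1), 6.43)
  expect_equal(compute_meld(exp(1), exp(1), exp(1)), 30.98)
  expect_equal(compute_meld(2, 3, 1.5),
               9.57 * log(2) + 3.78 * log(3) + 11.20 * log(1.5) + 6.43)
  expect_equal(round(compute_meld(2, 3, 1.5), 2), 21.76)

  ## flooring: sub-1 inputs behave like 1 unless disabled
  expect_equal(compute_meld(0.5, 0.8, 0.9), 6.43)
  expect_lt(compute_meld(0.5, 0.8, 0.9, floor_inputs = FALSE), 6.43)
  expect_error(compute_meld(0, 1, 1))

  ## monotone nondecreasing in each argument
  set.seed(2)
  base <- compute_meld(1.5, 2, 1.2)
  expect_true(all(compute_meld(seq(1.5, 5, by = 0.5), 2, 1.2) >= base))
  expect_true(all(compute_meld(1.5, seq(2, 6, by = 0.5), 1.2) >= base))
  expect_true(all(compute_meld(1.5, 2, seq(1.2, 3, by = 0.3)) >= base))
})
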