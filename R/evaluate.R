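#' Stratified k-fold partition
#'
#' Shuffles each class separately and deals indices round-robin, so fold class
#' proportions are within one sample of the global proportions and the folds
#' partition all indices.
#'
#' @param labels 0/1 outcome vector.
#' @param k number of folds; each class must have at least `k` members.
#' @param seed integer seed.
#' @return list of `k` integer index vectors.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  stopifnot(k >= 2)
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts < k)) stop("each class must have at least k members")
  with_seed(seed, {
    folds <- vector("list", k)
    for (cls in c(0, 1)) {
      idx <- sample(which(labels == cls))
      bucket <- rep_len(seq_len(k), length(idx))
      for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[bucket == f])
    }
    lapply(folds, sort)
  })
}

#' Area under the ROC curve
#'
#' The Mann-Whitney formulation: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, ties counting one half.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 outcomes; both classes must be present.
#' @return AUROC in \[0,1\].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity-constrained decision threshold
#'
#' Returns the largest threshold `t` (predict positive when `score >= t`)
#' whose sensitivity strictly exceeds `min_sens`, scanning the finite
#' candidate set of observed scores; if no threshold achieves it, the minimum
#' score is returned (everything predicted positive).
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 outcomes with at least one positive.
#' @param min_sens sensitivity to exceed (default 0.5).
#' @return the threshold.
#' @export
sensitivity_threshold <- function(scores, labels, min_sens = 0.5) {
  stopifnot(length(scores) > 0, length(scores) == length(labels),
            sum(labels == 1) >= 1)
  pos <- scores[labels == 1]
  cand <- sort(unique(scores), decreasing = TRUE)
  for (t in cand) {
    if (mean(pos >= t) > min_sens) return(t)
  }
  min(scores)
}

#' Accuracy and support-weighted precision, recall, F1
#'
#' Class-wise precision, recall and F1 averaged with class-support weights
#' (so weighted recall equals accuracy).
#'
#' @param pred,labels 0/1 vectors of equal, positive length.
#' @return list with `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(pred, labels) {
  stopifnot(length(pred) > 0, length(pred) == length(labels))
  per_class <- function(cls) {
    tp <- sum(pred == cls & labels == cls)
    p <- if (sum(pred == cls) == 0) 0 else tp / sum(pred == cls)
    r <- if (sum(labels == cls) == 0) 0 else tp / sum(labels == cls)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p = p, r = r, f = f, w = mean(labels == cls))
  }
  m0 <- per_class(0); m1 <- per_class(1)
  list(accuracy = mean(pred == labels),
       precision = m0["p"] * m0["w"] + m1["p"] * m1["w"],
       recall = m0["r"] * m0["w"] + m1["r"] * m1["w"],
       f1 = m0["f"] * m0["w"] + m1["f"] * m1["w"]) |>
    lapply(unname)
}

#' Per-subgroup performance and selected-classifier distribution
#'
#' For each rule: how many held-out patients it covers, the four
#' classification metrics on those patients (risk thresholded at
#' `threshold`), and the distribution of dynamically selected base
#' classifiers — the model-suitability report for that patient subgroup.
#'
#' @param fit a fitted [cades()] model.
#' @param test a [cohort_table()] of held-out patients.
#' @param rules list of [rule()]s (defaults to the model's mined rules).
#' @param threshold decision threshold on the risk score (default 0.5).
#' @return list with `metrics` (data.frame: rule, n, accuracy, precision,
#'   recall, f1 — metrics `NA` when n = 0) and `selection_histogram` (per
#'   rule, named counts over base classifiers).
#' @export
subgroup_report <- function(fit, test, rules = fit$rules, threshold = 0.5) {
  stopifnot(inherits(fit, "cades"))
  sel <- predict(fit, test, type = "selection")
  y <- outcome_values(test)
  pred <- (sel$risk >= threshold) * 1
  rows <- lapply(rules, function(r) {
    cov <- rule_coverage(r, test)
    if (length(cov) == 0) {
      return(data.frame(rule = format(r), n = 0, accuracy = NA_real_,
                        precision = NA_real_, recall = NA_real_, f1 = NA_real_))
    }
    m <- classification_metrics(pred[cov], y[cov])
    data.frame(rule = format(r), n = length(cov), accuracy = m$accuracy,
               precision = m$precision, recall = m$recall, f1 = m$f1)
  })
  hists <- lapply(rules, function(r) {
    cov <- rule_coverage(r, test)
    ids <- unlist(sel$selected[cov])
    tab <- table(factor(ids, levels = seq_along(fit$pool$bases)))
    stats::setNames(as.integer(tab),
                    vapply(fit$pool$bases, function(b)
                      paste0(b$family, "|", format(b$rule)), character(1)))
  })
  names(hists) <- vapply(rules, format, character(1))
  list(metrics = do.call(rbind, rows), selection_histogram = hists)
}

## Train one FULL single-family baseline on the screened features and return
## risk scores on each supplied table.
baseline_risk <- function(family, train, screened, seed, ...) {
  Xtr <- as.matrix(as.data.frame(unclass(train))[screened])
  rec <- fit_family(family, Xtr, outcome_values(train), seed)
  lapply(list(...), function(tab) {
    predict_family(rec, as.matrix(as.data.frame(unclass(tab))[screened]))
  })
}

#' Single holdout comparison of the framework against FULL baselines
#'
#' Generates (or takes) a cohort, splits it into stratified training and test
#' portions, fits [cades()] on the training portion, trains every
#' single-family baseline on the framework's base-training split with the
#' same screened features, and returns held-out AUROCs. Used by the dominance
#' and null-calibration experiments.
#'
#' @param cohort a [cohort_table()] or a [cohort_config()] to generate from.
#' @param seed integer seed for splitting and fitting.
#' @param test_fraction held-out fraction (default 0.25).
#' @param max_test evaluate AUROC on at most this many (stratified-sampled)
#'   test rows (default Inf).
#' @param ... passed to [cades()].
#' @return list with `framework_auroc`, `baseline_aurocs` (named by family),
#'   `fit`, and the test indices used.
#' @export
holdout_comparison <- function(cohort, seed = 1L, test_fraction = 0.25,
                               max_test = Inf, ...) {
  if (inherits(cohort, "cohort_config")) cohort <- generate_cohort(cohort)
  y <- outcome_values(cohort)
  k <- max(2L, round(1 / test_fraction))
  folds <- stratified_kfold(y, k, seed = derive_seed(seed, 21L))
  test_idx <- folds[[1]]
  if (length(test_idx) > max_test) {
    keep <- with_seed(derive_seed(seed, 23L),
                      sample(seq_along(test_idx), max_test))
    test_idx <- sort(test_idx[keep])
  }
  train_tab <- cohort_slice(cohort, sort(unlist(folds[-1])))
  test_tab <- cohort_slice(cohort, test_idx)

  fit <- cades(train_tab, seed = seed, ...)
  risk <- predict(fit, test_tab, type = "risk")
  fw_auc <- auroc(risk, outcome_values(test_tab))

  screened <- fit$screen$variable[fit$screen$selected]
  if (length(screened) == 0) screened <- predictor_cols(train_tab)
  base_train <- cohort_slice(train_tab, fit$train_indices)
  fams <- fit$params$families
  base_auc <- vapply(seq_along(fams), function(i) {
    br <- tryCatch(
      baseline_risk(fams[i], base_train, screened,
                    derive_seed(seed, 300L + i), test_tab),
      error = function(e) NULL)
    if (is.null(br)) return(NA_real_)
    auroc(br[[1]], outcome_values(test_tab))
  }, numeric(1))
  names(base_auc) <- fams
  list(framework_auroc = fw_auc, baseline_aurocs = base_auc,
       fit = fit, test_indices = test_idx)
}

#' Run the full cross-validated experiment
#'
#' Stratified k-fold cross-validation of the complete pipeline. Within each
#' fold, every fitted artifact — imputation donors, screening decisions,
#' mined rules, classifier pool, meta-classifier and decision threshold — is
#' derived from the training portion only; the held-out fold is imputed
#' against training donors and scored. Thresholds satisfying the sensitivity
#' constraint are chosen on the framework's DSEL predictions (training-side,
#' out-of-sample for the base classifiers), never on the test fold. The
#' eleven single-family FULL baselines are trained on the same base-training
#' split with the same screened features.
#'
#' @param config list with components: `cohort` (a [cohort_table()]) or
#'   `simulate` (a [cohort_config()]); optional `k_folds` (default 5),
#'   `min_sens` (default 0.5), `seed` (default 1), and `fit_args` (list of
#'   arguments forwarded to [cades()]).
#' @return an object of class `cades_cv`: per-fold and aggregate AUROC and
#'   accuracy for the framework and every baseline, chosen thresholds,
#'   per-subgroup metrics, selected-classifier distributions, seeds and a
#'   config fingerprint.
#' @export
run_experiment <- function(config) {
  cohort <- if (!is.null(config$cohort)) config$cohort
            else if (!is.null(config$simulate)) generate_cohort(config$simulate)
            else stop("config must name a cohort or a simulate block")
  k <- config$k_folds %||% 5L
  min_sens <- config$min_sens %||% 0.5
  seed <- config$seed %||% 1L
  fit_args <- config$fit_args %||% list()

  y <- outcome_values(cohort)
  folds <- stratified_kfold(y, k, seed = derive_seed(seed, 31L))
  fold_rows <- list(); sg_reports <- list()

  for (f in seq_len(k)) {
    stage <- "split"
    fold_res <- tryCatch({
      test_idx <- folds[[f]]
      train_raw <- cohort_slice(cohort, sort(unlist(folds[-f])))
      test_raw <- cohort_slice(cohort, test_idx)

      stage <- "impute"
      impute_k <- fit_args$impute_k %||% 5
      train_tab <- if (anyNA(as.data.frame(unclass(train_raw))[predictor_cols(train_raw)])) {
        knn_impute(train_raw, k = impute_k)
      } else train_raw
      test_tab <- if (anyNA(as.data.frame(unclass(test_raw))[predictor_cols(test_raw)])) {
        knn_impute(test_raw, k = impute_k, donors = train_tab)
      } else test_raw

      stage <- "fit"
      fit <- do.call(cades, c(list(data = train_tab,
                                   seed = derive_seed(seed, 100L + f)),
                              fit_args))

      stage <- "threshold"
      ydsel <- outcome_values(fit$dsel)
      dsel_pred <- predict(fit, fit$dsel, type = "risk")
      thr <- sensitivity_threshold(dsel_pred, ydsel, min_sens)

      stage <- "evaluate"
      risk <- predict(fit, test_tab, type = "risk")
      ytest <- outcome_values(test_tab)
      rows <- data.frame(fold = f, method = "cades",
                         auroc = auroc(risk, ytest),
                         accuracy = mean((risk >= thr) == ytest),
                         threshold = thr)

      stage <- "baselines"
      screened <- fit$screen$variable[fit$screen$selected]
      if (length(screened) == 0) screened <- predictor_cols(train_tab)
      base_train <- cohort_slice(train_tab, fit$train_indices)
      for (i in seq_along(fit$params$families)) {
        fam <- fit$params$families[i]
        br <- tryCatch(
          baseline_risk(fam, base_train, screened,
                        derive_seed(seed, 500L + 20L * f + i),
                        fit$dsel, test_tab),
          error = function(e) NULL)
        if (is.null(br)) {
          rows <- rbind(rows, data.frame(fold = f, method = fam,
                                         auroc = NA_real_,
                                         accuracy = NA_real_,
                                         threshold = NA_real_))
          next
        }
        bthr <- sensitivity_threshold(br[[1]], ydsel, min_sens)
        rows <- rbind(rows, data.frame(
          fold = f, method = fam,
          auroc = auroc(br[[2]], ytest),
          accuracy = mean((br[[2]] >= bthr) == ytest),
          threshold = bthr))
      }

      stage <- "subgroup_report"
      sg <- subgroup_report(fit, test_tab, threshold = thr)
      list(rows = rows, sg = sg)
    }, error = function(e) {
      stop(sprintf("fold %d failed at stage '%s': %s", f, stage,
                   conditionMessage(e)))
    })
    fold_rows[[f]] <- fold_res$rows
    sg_reports[[f]] <- fold_res$sg
  }

  per_fold <- do.call(rbind, fold_rows)
  agg <- do.call(rbind, lapply(split(per_fold, per_fold$method), function(d) {
    data.frame(method = d$method[1],
               auroc_mean = mean(d$auroc), auroc_min = min(d$auroc),
               auroc_max = max(d$auroc),
               accuracy_mean = mean(d$accuracy), accuracy_min = min(d$accuracy),
               accuracy_max = max(d$accuracy))
  }))
  rownames(agg) <- NULL
  structure(list(per_fold = per_fold, aggregate = agg,
                 subgroup_reports = sg_reports,
                 k_folds = k, seed = seed,
                 config_hash = fingerprint(config[setdiff(names(config), "cohort")])),
            class = "cades_cv")
}

#' @export
print.cades_cv <- function(x, ...) {
  cat(sprintf("Cross-validated comparison (%d folds, seed %s, config %s)\n",
              x$k_folds, format(x$seed), x$config_hash))
  agg <- x$aggregate
  agg <- agg[order(-agg$auroc_mean), ]
  agg[-1] <- lapply(agg[-1], round, 3)
  print(agg, row.names = FALSE)
  invisible(x)
}
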