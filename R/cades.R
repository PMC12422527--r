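#' Fit a complication-aware dynamic classifier selection model
#'
#' Runs the full training pipeline on a cohort: (1) k-nearest-neighbor
#' imputation if any predictor is missing; (2) univariate screening of
#' predictors across the outcome (Mann-Whitney U for continuous, chi-square /
#' Fisher exact for binary, retained at `p < alpha`); (3) exhaustive mining of
#' conjunction rules over the diagnosis columns to characterize patient
#' subgroups; (4) a stratified split of the data into a base-training portion
#' and a dynamic selection dataset (DSEL); (5) training of the heterogeneous
#' classifier pool on rule-defined subsets of the base-training portion; and
#' (6) leave-one-out meta-feature extraction on the DSEL and training of the
#' meta-classifier that scores per-patient classifier competence.
#'
#' @param data a [cohort_table()].
#' @param K feature-space region size (default 7).
#' @param Kp decision-space (output-profile) region size (default 5).
#' @param K_prime balanced diagnosis-space region size, even (default 10).
#' @param families base-classifier families (default all eleven,
#'   [classifier_families()]).
#' @param strategy rule-family pairing, `"cycle"` or `"cross"`
#'   (see [assign_algorithms()]).
#' @param feature_fraction per-base random feature-subspace fraction. The
#'   default 1.0 gives every base the full screened feature set: with the
#'   dozen-to-twenty predictors that survive screening on cohorts of this
#'   shape, random subspacing starves the base classifiers without adding
#'   useful diversity (rules and algorithm families already diversify the
#'   pool); lower it on wide cohorts.
#' @param undersample balance rule subsets by majority-class undersampling
#'   (default TRUE).
#' @param alpha univariate screening threshold (default 0.05).
#' @param min_support_frac rule support threshold as a fraction of training
#'   rows (default 0.15).
#' @param max_literals,min_per_class,max_rules rule-mining controls
#'   (see [mine_rules()]). The fit default `max_rules = 12` keeps roughly the
#'   rule budget per training dataset implied by a pooled count of 80 rules
#'   across ten cross-validation training sets; [mine_rules()] itself defaults
#'   to the pooled figure of 80.
#' @param meta_family meta-classifier family (default logistic regression).
#' @param dsel_fraction fraction of rows held out as DSEL (default 0.25).
#' @param impute_k neighbors for imputation (default 5).
#' @param epsilon competence-score argmax tolerance (default 1e-9).
#' @param seed integer seed controlling every random draw in the fit.
#' @return an object of class `cades` with `pool`, `meta`, `rules`, `screen`,
#'   `dsel`, and `params` components.
#' @seealso [predict.cades()], [run_experiment()]
#' @export
cades <- function(data, K = 7, Kp = 5, K_prime = 10,
                  families = classifier_families(),
                  strategy = c("cycle", "cross"),
                  feature_fraction = 1.0, undersample = TRUE,
                  alpha = 0.05, min_support_frac = 0.15, max_literals = 2,
                  min_per_class = 20, max_rules = 12,
                  meta_family = "logistic_regression",
                  dsel_fraction = 0.25, impute_k = 5, epsilon = 1e-9,
                  seed = 1L) {
  stopifnot(inherits(data, "cohort_table"))
  strategy <- match.arg(strategy)
  cl <- match.call()

  if (anyNA(as.data.frame(unclass(data))[predictor_cols(data)])) {
    data <- knn_impute(data, k = impute_k)
  }
  y <- outcome_values(data)
  if (length(unique(y)) < 2) stop("outcome must have both classes")

  screen <- univariate_screen(data, alpha = alpha)
  screened <- screen$variable[screen$selected]
  if (length(screened) == 0) {
    warning("no variable passed univariate screening; using all predictors")
    screened <- predictor_cols(data)
  }

  min_support <- max(1L, ceiling(min_support_frac * nrow(data)))
  rules <- mine_rules(data, min_support = min_support,
                      max_literals = max_literals,
                      min_per_class = min_per_class, max_rules = max_rules)
  if (length(rules) == 0) {
    warning("no subgroup rule met the support constraints; pool is FULL-only")
  }

  ## stratified base-training / DSEL split
  k_split <- max(2L, round(1 / dsel_fraction))
  folds <- stratified_kfold(y, k = k_split, seed = derive_seed(seed, 7L))
  dsel_idx <- sort(folds[[1]])
  base_idx <- sort(unlist(folds[-1]))
  train_tab <- cohort_slice(data, base_idx)
  dsel_tab <- cohort_slice(data, dsel_idx)

  assignments <- if (length(rules) > 0) {
    assign_algorithms(rules, families, strategy)
  } else {
    lapply(families, function(f) list(rule = rule(), family = f))
  }
  pool <- train_pool(train_tab, assignments, feature_names = screened,
                     feature_fraction = feature_fraction,
                     undersample = undersample,
                     seed = derive_seed(seed, 11L))

  meta_ds <- build_meta_dataset(pool, dsel_tab, K = K, Kp = Kp,
                                K_prime = K_prime)
  lambda <- train_meta(meta_ds, family = meta_family,
                       seed = derive_seed(seed, 13L))

  structure(list(pool = pool, meta = lambda, rules = rules, screen = screen,
                 dsel = dsel_tab, train_indices = base_idx,
                 dsel_indices = dsel_idx,
                 params = list(K = K, Kp = Kp, K_prime = K_prime,
                               families = families, strategy = strategy,
                               feature_fraction = feature_fraction,
                               undersample = undersample, alpha = alpha,
                               min_support = min_support,
                               max_literals = max_literals,
                               min_per_class = min_per_class,
                               max_rules = max_rules,
                               meta_family = meta_family,
                               impute_k = impute_k, epsilon = epsilon,
                               seed = seed),
                 call = cl),
            class = "cades")
}

#' Predict readmission risk with dynamic classifier selection
#'
#' For every new patient, meta-features are extracted against the model's
#' DSEL, the meta-classifier scores the competence of each pool member, the
#' argmax set (within tolerance) is selected, and its predictions are
#' aggregated (majority vote; the continuous risk score is the mean
#' positive-class posterior over the selection).
#'
#' @param object a fitted [cades()] model.
#' @param newdata a [cohort_table()]; imputed against the model's training
#'   DSEL/base data if it carries missing values.
#' @param type `"response"` (default: data.frame with `label` from the vote
#'   and continuous `risk`), `"risk"` (numeric vector) or `"selection"`
#'   (adds the selected classifier indices per patient).
#' @param ... unused.
#' @return see `type`.
#' @export
predict.cades <- function(object, newdata,
                          type = c("response", "risk", "selection"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "cohort_table"))
  if (anyNA(as.data.frame(unclass(newdata))[predictor_cols(newdata)])) {
    newdata <- knn_impute(newdata, k = object$params$impute_k,
                          donors = object$dsel)
  }
  engine <- meta_engine(object$pool, object$dsel)
  p <- object$params
  mb <- meta_features_batch(engine, newdata, p$K, p$Kp, p$K_prime)
  comp <- predict_meta(object$meta, mb$V)
  m <- length(object$pool$bases)
  scoresMat <- matrix(comp, ncol = m, byrow = TRUE)  # instance-major rows
  out <- select_batch(scoresMat, mb$profiles, p$epsilon)
  switch(type,
         risk = out$risk,
         response = data.frame(label = out$label, risk = out$risk),
         selection = list(label = out$label, risk = out$risk,
                          selected = out$selected, scores = scoresMat))
}

#' @export
print.cades <- function(x, ...) {
  cat("Complication-aware dynamic classifier selection model\n")
  cat(sprintf("  pool: %d base classifiers (%d subgroup rules + FULL fallbacks)\n",
              length(x$pool$bases), length(x$rules)))
  cat(sprintf("  screened predictors: %d of %d\n",
              sum(x$screen$selected), nrow(x$screen)))
  cat(sprintf("  DSEL: %d patients; K=%d, Kp=%d, K'=%d; meta: %s\n",
              nrow(x$dsel), x$params$K, x$params$Kp, x$params$K_prime,
              x$params$meta_family))
  invisible(x)
}

#' @export
summary.cades <- function(object, ...) {
  P <- output_profile(object$pool, object$dsel)
  yd <- outcome_values(object$dsel)
  acc <- colMeans((P >= 0.5) == matrix(yd, nrow(P), ncol(P)))
  s <- list(model = object,
            base_summary = data.frame(
              index = vapply(object$pool$bases, `[[`, integer(1), "index"),
              family = vapply(object$pool$bases, `[[`, character(1), "family"),
              rule = vapply(object$pool$bases, function(b) format(b$rule),
                            character(1)),
              n_train = vapply(object$pool$bases, `[[`, integer(1), "n_train"),
              dsel_accuracy = round(acc, 4)))
  class(s) <- "summary.cades"
  s
}

#' @export
print.summary.cades <- function(x, ...) {
  print(x$model)
  cat("\nBase classifiers (accuracy on the DSEL):\n")
  print(x$base_summary, row.names = FALSE)
  invisible(x)
}
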