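#' The eleven base-classifier algorithm families
#'
#' Family names accepted by [assign_algorithms()] and [train_pool()]:
#' naive Bayes, k-nearest neighbors, logistic regression, linear and quadratic
#' discriminant analysis, random forest, extremely randomized trees, AdaBoost
#' (SAMME over depth-1 trees), gradient boosting, leaf-wise histogram gradient
#' boosting (LightGBM-style growth), and depth-wise histogram gradient
#' boosting with row/column subsampling (XGBoost-style).
#'
#' @return character vector of family names.
#' @export
classifier_families <- function() {
  c("naive_bayes", "knn", "logistic_regression", "lda", "qda",
    "random_forest", "extra_trees", "adaboost", "gradient_boosting",
    "lightgbm_family", "xgboost_family")
}

## Drop zero-variance columns; families needing per-class variance also drop
## columns constant within either class. Returns kept column names.
usable_columns <- function(X, y, per_class = FALSE) {
  keep <- vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    if (stats::var(v) == 0) return(FALSE)
    if (per_class) {
      if (stats::var(v[y == 1]) == 0 || stats::var(v[y == 0]) == 0) return(FALSE)
    }
    TRUE
  }, logical(1))
  colnames(X)[keep]
}

## SAMME AdaBoost over rpart stumps. Returns list(stumps, alphas).
fit_adaboost <- function(X, y, rounds = 50) {
  df <- as.data.frame(X)
  df$.y <- factor(y, levels = c(0, 1))
  n <- nrow(df)
  w <- rep(1 / n, n)
  ctrl <- rpart::rpart.control(maxdepth = 1, minsplit = 2, cp = 0, xval = 0)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- as.numeric(stats::predict(fit, df, type = "class") == "1")
    err <- sum(w * (pred != y))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 0.5 && m > 1) break
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
    if (err <= 1e-9) break
  }
  list(stumps = stumps, alphas = alphas)
}

predict_adaboost <- function(model, X) {
  df <- as.data.frame(X)
  f <- numeric(nrow(df))
  for (m in seq_along(model$stumps)) {
    h <- as.numeric(stats::predict(model$stumps[[m]], df, type = "class") == "1")
    f <- f + model$alphas[m] * (2 * h - 1)
  }
  s <- sum(model$alphas)
  if (s > 0) f <- f / s
  1 / (1 + exp(-2 * f))
}

xgb_params <- function(family) {
  base <- list(objective = "binary:logistic", eta = 0.1, nthread = 1)
  switch(family,
    gradient_boosting = c(base, list(max_depth = 3, tree_method = "exact",
                                     subsample = 1)),
    lightgbm_family = c(base, list(tree_method = "hist",
                                   grow_policy = "lossguide",
                                   max_leaves = 31, max_depth = 0)),
    xgboost_family = c(base, list(tree_method = "hist", max_depth = 5,
                                  subsample = 0.8, colsample_bytree = 0.8)))
}

## Fit one family on a numeric feature matrix. Returns a model record or
## signals an error (caller decides whether to skip the base).
fit_family <- function(family, X, y, seed) {
  stopifnot(family %in% classifier_families())
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stop("training subset has a single outcome class")
  with_seed(seed, {
    per_class <- family %in% c("naive_bayes", "qda", "lda")
    kept <- usable_columns(X, y, per_class = per_class)
    if (length(kept) == 0) stop("no usable feature columns for family ", family)
    Xk <- X[, kept, drop = FALSE]
    fac <- factor(y, levels = c(0, 1))
    model <- switch(family,
      naive_bayes = e1071::naiveBayes(x = as.data.frame(Xk), y = fac),
      knn = {
        mu <- colMeans(Xk); sdv <- apply(Xk, 2, stats::sd); sdv[sdv == 0] <- 1
        list(train = sweep(sweep(Xk, 2, mu), 2, sdv, "/"),
             y = y, mu = mu, sd = sdv, k = min(5, nrow(Xk)))
      },
      logistic_regression = {
        df <- as.data.frame(Xk); df$.y <- y
        suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      },
      lda = MASS::lda(Xk, grouping = fac),
      qda = MASS::qda(Xk, grouping = fac),
      random_forest = randomForest::randomForest(x = Xk, y = fac, ntree = 200),
      extra_trees = ranger::ranger(x = as.data.frame(Xk), y = fac,
                                   probability = TRUE, num.trees = 200,
                                   splitrule = "extratrees",
                                   num.random.splits = 1,
                                   seed = as.integer(seed) %% 2147483647,
                                   num.threads = 1),
      adaboost = fit_adaboost(Xk, y),
      gradient_boosting = ,
      lightgbm_family = ,
      xgboost_family = xgboost::xgb.train(
        params = xgb_params(family),
        data = xgboost::xgb.DMatrix(Xk, label = y, nthread = 1),
        nrounds = 60, verbose = 0)
    )
    list(family = family, model = model, kept = kept)
  })
}

## Positive-class probability of a fitted family record on new rows.
predict_family <- function(record, X) {
  X <- as.matrix(X)[, record$kept, drop = FALSE]
  family <- record$family
  model <- record$model
  p <- switch(family,
    naive_bayes = stats::predict(model, as.data.frame(X), type = "raw")[, "1"],
    knn = {
      ## tie-stable kNN: exact distances, ties broken by lower train index,
      ## positive probability = neighbor mean; chunked to bound memory
      Xz <- sweep(sweep(X, 2, model$mu), 2, model$sd, "/")
      n <- nrow(Xz)
      out <- numeric(n)
      tr2 <- rowSums(model$train^2)
      for (start in seq(1, n, by = 512)) {
        idx <- start:min(start + 511, n)
        D <- outer(rowSums(Xz[idx, , drop = FALSE]^2), tr2, "+") -
          2 * tcrossprod(Xz[idx, , drop = FALSE], model$train)
        out[idx] <- apply(D, 1, function(d) {
          nb <- order(d, seq_along(d))[seq_len(model$k)]
          mean(model$y[nb])
        })
      }
      out
    },
    logistic_regression = as.numeric(suppressWarnings(
      stats::predict(model, as.data.frame(X), type = "response"))),
    lda = stats::predict(model, X)$posterior[, "1"],
    qda = stats::predict(model, X)$posterior[, "1"],
    random_forest = stats::predict(model, X, type = "prob")[, "1"],
    extra_trees = stats::predict(model, as.data.frame(X),
                                 num.threads = 1)$predictions[, "1"],
    adaboost = predict_adaboost(model, X),
    gradient_boosting = ,
    lightgbm_family = ,
    xgboost_family = stats::predict(model, xgboost::xgb.DMatrix(X, nthread = 1))
  )
  p <- as.numeric(p)
  pmin(pmax(p, 0), 1)
}
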