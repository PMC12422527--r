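## ---- regions of competence -------------------------------------------------

as_feature_matrix <- function(x, feature_names) {
  if (inherits(x, "cohort_table") || is.data.frame(x)) {
    df <- as.data.frame(unclass(x), stringsAsFactors = FALSE)
    missing_cols <- setdiff(feature_names, names(df))
    if (length(missing_cols) > 0) {
      stop("instance lacks column(s): ", paste(missing_cols, collapse = ", "))
    }
    as.matrix(df[feature_names])
  } else {
    m <- matrix(x[feature_names], nrow = 1)
    colnames(m) <- feature_names
    m
  }
}

## squared Euclidean cross-distances
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Feature-space region of competence
#'
#' The K nearest rows of the dynamic selection dataset (DSEL) to the query
#' instance, by Euclidean distance over z-scored feature columns
#' (standardization statistics fit on the DSEL). Distance ties break toward
#' the lower DSEL row index.
#'
#' @param x a 1-row [cohort_table()]/data.frame or named numeric vector.
#' @param dsel the DSEL [cohort_table()].
#' @param K neighborhood size, at most `nrow(dsel)`.
#' @param feature_names feature columns spanning the space; defaults to all
#'   DSEL predictors.
#' @return a `cades_region`: list with `kind = "feature"`, `members` (DSEL row
#'   indices, nearest first) and `distances`.
#' @export
region_feature <- function(x, dsel, K, feature_names = predictor_cols(dsel)) {
  if (nrow(dsel) == 0) stop("DSEL is empty")
  stopifnot(K >= 1, K <= nrow(dsel))
  Xd <- as_feature_matrix(dsel, feature_names)
  mu <- colMeans(Xd)
  sdv <- apply(Xd, 2, stats::sd); sdv[!is.finite(sdv) | sdv == 0] <- 1
  Zd <- sweep(sweep(Xd, 2, mu), 2, sdv, "/")
  Zq <- sweep(sweep(as_feature_matrix(x, feature_names), 2, mu), 2, sdv, "/")
  d <- sqrt(cross_dist2(Zq, Zd)[1, ])
  ord <- order(d, seq_along(d))[seq_len(K)]
  structure(list(kind = "feature", members = ord, distances = d[ord]),
            class = "cades_region")
}

#' Balanced diagnosis-space region of competence
#'
#' The complication-aware region: the `K_prime/2` nearest positive-outcome
#' and `K_prime/2` nearest negative-outcome DSEL rows by Hamming distance
#' over the binary diagnosis columns only, so base-classifier skill around a
#' patient's complication/comorbidity pattern is judged on a class-balanced
#' sample. Ties break toward the lower DSEL row index.
#'
#' @param x a 1-row [cohort_table()]/data.frame or named numeric vector over
#'   the diagnosis columns.
#' @param dsel the DSEL [cohort_table()]; must hold at least `K_prime/2` rows
#'   of each outcome class.
#' @param K_prime even region size.
#' @return a `cades_region` with `kind = "diagnosis"`; members are ordered
#'   positives-then-negatives, each block by nondecreasing distance.
#' @export
region_diagnosis <- function(x, dsel, K_prime) {
  stopifnot(K_prime >= 2, K_prime %% 2 == 0)
  dcols <- diagnosis_cols(dsel)
  y <- outcome_values(dsel)
  half <- K_prime / 2
  if (sum(y == 1) < half || sum(y == 0) < half) {
    stop("DSEL needs at least K_prime/2 rows of each outcome class")
  }
  Bd <- as_feature_matrix(dsel, dcols)
  Bq <- as_feature_matrix(x, dcols)
  ham <- as.numeric(length(dcols) - tcrossprod(Bq, Bd) -
                      tcrossprod(1 - Bq, 1 - Bd))
  pick <- function(rows) rows[order(ham[rows], rows)][seq_len(half)]
  members <- c(pick(which(y == 1)), pick(which(y == 0)))
  structure(list(kind = "diagnosis", members = members,
                 distances = ham[members]),
            class = "cades_region")
}

## ---- meta-feature engine ---------------------------------------------------

## Precompute everything about (pool, DSEL) that meta-feature extraction
## reuses: z-scoring stats, feature/diagnosis matrices, output profiles,
## per-base correctness and true-class posteriors on the DSEL.
meta_engine <- function(pool, dsel) {
  feats <- pool$feature_names
  Xd <- as_feature_matrix(dsel, feats)
  mu <- colMeans(Xd)
  sdv <- apply(Xd, 2, stats::sd); sdv[!is.finite(sdv) | sdv == 0] <- 1
  Zd <- sweep(sweep(Xd, 2, mu), 2, sdv, "/")
  dcols <- diagnosis_cols(dsel)
  Bd <- as_feature_matrix(dsel, dcols)
  yd <- outcome_values(dsel)
  P <- output_profile(pool, dsel)              # |DSEL| x m
  predL <- (P >= 0.5) * 1
  corr <- t(predL == yd) * 1                   # m x |DSEL|
  postTrue <- t(ifelse(matrix(yd, nrow(P), ncol(P)) == 1, P, 1 - P))
  list(pool = pool, dsel = dsel, feats = feats, mu = mu, sd = sdv,
       Zd = Zd, dcols = dcols, Bd = Bd, yd = yd,
       P = P, corr = corr, postTrue = postTrue, m = ncol(P))
}

## Meta-feature matrix for a batch of query instances.
## Returns list(V = (n*m) x (2K+Kp+3) matrix, base = base index per row,
## instance = query index per row). Row order: instance-major, pool order
## within instance. `exclude_self = TRUE` treats query j as DSEL row j and
## removes it from its own regions (leave-one-out meta-training).
meta_features_batch <- function(engine, query, K, Kp, K_prime,
                                exclude_self = FALSE) {
  stopifnot(K >= 1, K <= nrow(engine$Zd) - exclude_self,
            Kp >= 1, K_prime %% 2 == 0)
  half <- K_prime / 2
  Zq <- sweep(sweep(as_feature_matrix(query, engine$feats), 2, engine$mu),
              2, engine$sd, "/")
  Bq <- as_feature_matrix(query, engine$dcols)
  Pq <- output_profile(engine$pool, query)
  n <- nrow(Zq); m <- engine$m
  excl <- if (exclude_self) seq_len(n) else NULL

  Df <- cross_dist2(Zq, engine$Zd)
  Dp <- cross_dist2(Pq, engine$P)
  Dh <- length(engine$dcols) - tcrossprod(Bq, engine$Bd) -
    tcrossprod(1 - Bq, 1 - engine$Bd)

  pos <- which(engine$yd == 1); neg <- which(engine$yd == 0)
  if (length(pos) < half + exclude_self || length(neg) < half + exclude_self) {
    stop("DSEL needs at least K_prime/2 rows of each outcome class")
  }

  V <- matrix(NA_real_, n * m, 2 * K + Kp + 3)
  conf_q <- ifelse(Pq >= 0.5, Pq, 1 - Pq)       # n x m, f5
  for (j in seq_len(n)) {
    df <- Df[j, ]; dp <- Dp[j, ]; dh <- Dh[j, ]
    if (!is.null(excl)) { df[excl[j]] <- Inf; dp[excl[j]] <- Inf; dh[excl[j]] <- Inf }
    theta <- order(df, seq_along(df))[seq_len(K)]
    pi_nb <- order(dp, seq_along(dp))[seq_len(Kp)]
    tpos <- pos[order(dh[pos], pos)][seq_len(half)]
    tneg <- neg[order(dh[neg], neg)][seq_len(half)]
    f1 <- engine$corr[, theta, drop = FALSE]
    f2 <- engine$postTrue[, theta, drop = FALSE]
    f4 <- engine$corr[, pi_nb, drop = FALSE]
    f6 <- rowMeans(engine$corr[, c(tpos, tneg), drop = FALSE])
    rows <- (j - 1L) * m + seq_len(m)
    V[rows, ] <- cbind(f1, f2, rowMeans(f1), f4, conf_q[j, ], f6)
  }
  colnames(V) <- c(paste0("f1_", seq_len(K)), paste0("f2_", seq_len(K)), "f3",
                   paste0("f4_", seq_len(Kp)), "f5", "f6")
  list(V = V, base = rep(seq_len(m), n), instance = rep(seq_len(n), each = m),
       profiles = Pq)
}

#' Meta-features of one base classifier for one instance
#'
#' Assembles the meta-feature vector `v = (f1, f2, f3, f4, f5, f6)` for base
#' classifier `i` and a query instance: per-neighbor correctness indicators
#' over the feature-space region (`f1`, K entries), the base's posterior for
#' each neighbor's true class (`f2`, K entries), their mean (`f3`),
#' correctness over the `Kp` nearest DSEL rows in output-profile (decision)
#' space (`f4`), the base's confidence in its own prediction for the query
#' (`f5`), and its accuracy over the balanced diagnosis-space region (`f6`).
#' All entries lie in \[0,1\] and the vector has length `2K + Kp + 3`.
#'
#' @param pool a [train_pool()] result.
#' @param i base classifier position in the pool (1-based).
#' @param x a 1-row [cohort_table()]/data.frame.
#' @param dsel the DSEL [cohort_table()].
#' @param K,Kp,K_prime region sizes (feature space, decision space, balanced
#'   diagnosis space).
#' @return list with the full vector `v` and the named blocks `f1..f6`.
#' @export
extract_meta_features <- function(pool, i, x, dsel, K = 7, Kp = 5, K_prime = 10) {
  engine <- meta_engine(pool, dsel)
  mb <- meta_features_batch(engine, x, K, Kp, K_prime)
  v <- mb$V[mb$base == i & mb$instance == 1L, ]
  list(v = v,
       f1 = unname(v[seq_len(K)]),
       f2 = unname(v[K + seq_len(K)]),
       f3 = unname(v[2 * K + 1]),
       f4 = unname(v[2 * K + 1 + seq_len(Kp)]),
       f5 = unname(v[2 * K + Kp + 2]),
       f6 = unname(v[2 * K + Kp + 3]))
}

#' Build the meta-training dataset
#'
#' One meta-example per (base classifier, DSEL instance) pair: the
#' meta-feature vector plus the correctness label `alpha` (1 when the base
#' classifies the instance correctly). When extracting features for DSEL
#' instance j, the instance is excluded from its own regions (leave-one-out)
#' to avoid self-neighbor leakage.
#'
#' @param pool a [train_pool()] result (trained on rows disjoint from `dsel`).
#' @param dsel the DSEL [cohort_table()].
#' @inheritParams extract_meta_features
#' @return data.frame with `classifier_index` (1-based pool position),
#'   `instance_index`, feature columns `f*`, and `alpha`.
#' @export
build_meta_dataset <- function(pool, dsel, K = 7, Kp = 5, K_prime = 10) {
  engine <- meta_engine(pool, dsel)
  mb <- meta_features_batch(engine, dsel, K, Kp, K_prime, exclude_self = TRUE)
  alpha <- as.numeric(engine$corr[cbind(mb$base, mb$instance)])
  out <- data.frame(classifier_index = mb$base, instance_index = mb$instance)
  out <- cbind(out, as.data.frame(mb$V))
  out$alpha <- alpha
  out
}

## ---- meta-classifier -------------------------------------------------------

#' Train the meta-classifier
#'
#' Fits the competence model mapping meta-feature vectors to the probability
#' that a base classifier will classify the instance correctly.
#'
#' @param meta a [build_meta_dataset()] data.frame (both alpha values must be
#'   present).
#' @param family `"logistic_regression"` (default), `"naive_bayes"` or
#'   `"random_forest"`.
#' @param seed integer seed.
#' @return an object of class `cades_meta`.
#' @export
train_meta <- function(meta, family = c("logistic_regression", "naive_bayes",
                                        "random_forest"), seed = 1L) {
  family <- match.arg(family)
  vcols <- setdiff(names(meta), c("classifier_index", "instance_index", "alpha"))
  if (length(unique(meta$alpha)) < 2) {
    stop("meta-dataset must contain both alpha values")
  }
  fam_key <- switch(family, logistic_regression = "logistic_regression",
                    naive_bayes = "naive_bayes", random_forest = "random_forest")
  record <- fit_family(fam_key, as.matrix(meta[vcols]), meta$alpha,
                       derive_seed(seed, 99L))
  structure(list(family = family, record = record, vcols = vcols),
            class = "cades_meta")
}

#' Competence probabilities from a fitted meta-classifier
#'
#' @param lambda a [train_meta()] result.
#' @param V meta-feature matrix (rows = meta-examples).
#' @return numeric vector in \[0,1\].
#' @export
predict_meta <- function(lambda, V) {
  stopifnot(inherits(lambda, "cades_meta"))
  V <- as.matrix(V)
  colnames(V) <- lambda$vcols
  predict_family(lambda$record, V)
}

#' Competence scores of every pool member for one instance
#'
#' Extracts fresh meta-features for the query against the DSEL and maps them
#' through the meta-classifier, yielding one competence probability per base
#' classifier in pool order.
#'
#' @param lambda a [train_meta()] result.
#' @param pool a [train_pool()] result.
#' @param x a 1-row [cohort_table()]/data.frame.
#' @param dsel the DSEL [cohort_table()].
#' @inheritParams extract_meta_features
#' @return numeric vector of length pool size.
#' @export
score_competences <- function(lambda, pool, x, dsel, K = 7, Kp = 5,
                              K_prime = 10) {
  engine <- meta_engine(pool, dsel)
  mb <- meta_features_batch(engine, x, K, Kp, K_prime)
  predict_meta(lambda, mb$V)
}

## ---- selection and aggregation ---------------------------------------------

#' Select competent classifiers and predict
#'
#' The selected ensemble is the argmax set of competence scores within
#' tolerance `epsilon`. A single selected base predicts directly; otherwise
#' the selected bases' labels are aggregated by majority vote, a vote tie
#' resolved toward the class with the larger mean posterior over the
#' selection, and a residual tie toward the positive class. The continuous
#' risk score is the mean positive-class posterior over the selection.
#'
#' @param scores finite competence score vector, one per pool member.
#' @param pool a [train_pool()] result.
#' @param x a 1-row [cohort_table()]/data.frame.
#' @param epsilon argmax tolerance (default 1e-9).
#' @return a `cades_selection`: list with `competence_scores`,
#'   `selected_indices` (1-based pool positions), `predicted_label` and
#'   `risk_score`.
#' @export
select_and_predict <- function(scores, pool, x, epsilon = 1e-9) {
  stopifnot(all(is.finite(scores)), length(scores) == length(pool$bases))
  probs <- output_profile(pool, x)[1, ]
  sel <- select_one(scores, probs, epsilon)
  structure(c(list(competence_scores = scores), sel),
            class = "cades_selection")
}

## Core selection rule on one instance given scores and base posteriors.
select_one <- function(scores, probs, epsilon) {
  scores <- unname(scores); probs <- unname(probs)
  sel <- which(scores >= max(scores) - epsilon)
  labels <- (probs[sel] >= 0.5) * 1
  risk <- mean(probs[sel])
  n1 <- sum(labels == 1); n0 <- length(labels) - n1
  label <- if (n1 > n0) 1L else if (n0 > n1) 0L else {
    if (risk > 0.5) 1L else if (risk < 0.5) 0L else 1L
  }
  list(selected_indices = sel, predicted_label = label, risk_score = risk)
}

## Batch selection over precomputed score and posterior matrices (n x m).
select_batch <- function(scoresMat, probsMat, epsilon) {
  n <- nrow(scoresMat)
  label <- integer(n); risk <- numeric(n)
  selected <- vector("list", n)
  for (j in seq_len(n)) {
    s <- select_one(scoresMat[j, ], probsMat[j, ], epsilon)
    label[j] <- s$predicted_label
    risk[j] <- s$risk_score
    selected[[j]] <- s$selected_indices
  }
  list(label = label, risk = risk, selected = selected)
}
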