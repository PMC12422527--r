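#' Balance a training subset by undersampling the majority class
#'
#' Keeps every minority-class row and samples majority-class rows without
#' replacement down to the minority count. Already-balanced input is returned
#' unchanged. Deterministic given `seed`.
#'
#' @param indices integer row indices.
#' @param labels 0/1 outcome labels aligned with `indices`.
#' @param seed integer seed.
#' @return sorted integer subset of `indices`.
#' @export
undersample_indices <- function(indices, labels, seed) {
  stopifnot(length(indices) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  if (n1 == n0) return(sort(indices))
  minority <- if (n1 < n0) 1 else 0
  keep <- indices[labels == minority]
  maj <- indices[labels != minority]
  picked <- with_seed(seed, sample(maj, length(keep)))
  sort(c(keep, picked))
}

#' Pair subgroup rules with algorithm families
#'
#' `cycle` assigns one family per rule, round-robin in rule order, bounding
#' pool size at `length(rules) + length(families)`; `cross` creates every
#' rule-family pair. One full-training-set (empty-rule) pair per family is
#' always appended so every test instance has competent fallbacks even when
#' it matches no mined rule.
#'
#' @param rules non-empty list of [rule()] objects.
#' @param families character vector of family names
#'   (see [classifier_families()]).
#' @param strategy `"cycle"` (default) or `"cross"`.
#' @return list of `list(rule =, family =)` pairs.
#' @export
assign_algorithms <- function(rules, families = classifier_families(),
                              strategy = c("cycle", "cross")) {
  strategy <- match.arg(strategy)
  if (length(rules) == 0) stop("rules must be non-empty")
  stopifnot(length(families) > 0, all(families %in% classifier_families()))
  pairs <- if (strategy == "cycle") {
    lapply(seq_along(rules), function(k) {
      list(rule = rules[[k]], family = families[[(k - 1L) %% length(families) + 1L]])
    })
  } else {
    unlist(lapply(rules, function(r) {
      lapply(families, function(f) list(rule = r, family = f))
    }), recursive = FALSE)
  }
  full <- lapply(families, function(f) list(rule = rule(), family = f))
  c(pairs, full)
}

#' Train the heterogeneous classifier pool
#'
#' Each assignment trains one base classifier on the rows its rule covers in
#' `train` (optionally balanced by [undersample_indices()]) using a seeded
#' random feature subset of size `ceiling(feature_fraction * p)` drawn from
#' the `feature_names` candidates, where `p` is the candidate count after
#' excluding the diagnosis columns appearing in the base's own rule.
#' Assignments whose subset holds a single outcome class (or whose family
#' cannot be fit, e.g. QDA on a within-class-constant subset) are skipped
#' with a warning. Deterministic given `seed`.
#'
#' @param train a complete [cohort_table()].
#' @param assignments output of [assign_algorithms()].
#' @param feature_names candidate predictor columns (typically the
#'   univariate-screened selection); defaults to all predictors.
#' @param feature_fraction fraction of candidate features per base
#'   (default 0.8).
#' @param undersample balance each training subset by majority-class
#'   undersampling (default TRUE); applied uniformly so base posteriors stay
#'   comparably calibrated across the pool.
#' @param seed integer seed.
#' @return an object of class `cades_pool`.
#' @export
train_pool <- function(train, assignments, feature_names = NULL,
                       feature_fraction = 0.8, undersample = TRUE, seed = 1L) {
  stopifnot(inherits(train, "cohort_table"), length(assignments) > 0,
            feature_fraction > 0, feature_fraction <= 1)
  if (anyNA(as.data.frame(unclass(train))[predictor_cols(train)])) {
    stop("train must be complete; impute first")
  }
  feature_names <- feature_names %||% predictor_cols(train)
  stopifnot(all(feature_names %in% predictor_cols(train)))
  y <- outcome_values(train)
  Xall <- as.matrix(as.data.frame(unclass(train))[feature_names])
  bases <- list()
  for (a in seq_along(assignments)) {
    asg <- assignments[[a]]
    cov <- rule_coverage(asg$rule, train)
    if (length(unique(y[cov])) < 2) {
      warning(sprintf("skipping base %d (%s on '%s'): single outcome class",
                      a, asg$family, format(asg$rule)))
      next
    }
    rows <- if (undersample) {
      undersample_indices(cov, y[cov], derive_seed(seed, 2L * a))
    } else cov
    cand <- setdiff(feature_names, names(asg$rule$literals))
    nf <- ceiling(feature_fraction * length(cand))
    feats <- if (nf >= length(cand)) cand else {
      sort(with_seed(derive_seed(seed, 2L * a + 1L), sample(cand, nf)))
    }
    record <- tryCatch(
      fit_family(asg$family, Xall[rows, feats, drop = FALSE], y[rows],
                 derive_seed(seed, 1000L + a)),
      error = function(e) {
        warning(sprintf("skipping base %d (%s on '%s'): %s",
                        a, asg$family, format(asg$rule), conditionMessage(e)))
        NULL
      })
    if (is.null(record)) next
    bases[[length(bases) + 1L]] <- list(
      index = length(bases),
      family = asg$family,
      rule = asg$rule,
      feature_names = feats,
      record = record,
      n_train = length(rows),
      class_counts = c(neg = sum(y[rows] == 0), pos = sum(y[rows] == 1)))
  }
  if (length(bases) == 0) stop("empty pool: every assignment was skipped")
  structure(list(bases = bases, feature_names = feature_names),
            class = "cades_pool")
}

#' @export
print.cades_pool <- function(x, ...) {
  cat(sprintf("<cades_pool> %d base classifiers\n", length(x$bases)))
  for (b in x$bases) {
    cat(sprintf("  [%d] %-20s n=%-5d rule: %s\n",
                b$index, b$family, b$n_train, format(b$rule)))
  }
  invisible(x)
}

#' Positive-class probabilities of every pool member
#'
#' The output profile of an instance is the vector of all base classifiers'
#' positive-class probabilities, in pool order; profiles locate instances in
#' the pool's decision space.
#'
#' @param pool a fitted [train_pool()] result.
#' @param newdata a [cohort_table()] (or data.frame carrying the pool's
#'   feature columns).
#' @return numeric matrix, `nrow(newdata)` x pool size, entries in \[0,1\].
#' @export
output_profile <- function(pool, newdata) {
  stopifnot(inherits(pool, "cades_pool"))
  df <- as.data.frame(unclass(newdata), stringsAsFactors = FALSE)
  missing_cols <- setdiff(pool$feature_names, names(df))
  if (length(missing_cols) > 0) {
    stop("newdata lacks pool feature column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(df[pool$feature_names])
  out <- vapply(pool$bases, function(b) {
    predict_family(b$record, X[, b$feature_names, drop = FALSE])
  }, numeric(nrow(X)))
  matrix(out, nrow = nrow(X),
         dimnames = list(NULL, vapply(pool$bases, function(b)
           paste0("c", b$index), character(1))))
}

#' Pool manifest
#'
#' Per-base provenance (family, rule text, features, training-row and class
#' counts) as a YAML-serializable list; written to `path` when given.
#'
#' @param pool a `cades_pool`.
#' @param path optional YAML output path.
#' @return the manifest list, invisibly when `path` is given.
#' @export
pool_manifest <- function(pool, path = NULL) {
  m <- lapply(pool$bases, function(b) {
    list(index = b$index, family = b$family,
         rule = format(b$rule, with_support = TRUE),
         features = b$feature_names,
         n_train = b$n_train,
         class_counts = as.list(b$class_counts))
  })
  if (!is.null(path)) {
    yaml::write_yaml(m, path)
    return(invisible(m))
  }
  m
}
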