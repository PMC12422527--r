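## Small cohort fixtures built in code.

## Tiny deterministic cohort: two diagnosis columns with a fixed pattern,
## two labs, one demographic, outcome supplied by the caller.
toy_cohort <- function(A = c(1, 1, 1, 1, 0, 0, 0, 0),
                       B = c(1, 0, 1, 0, 1, 0, 1, 0),
                       y = c(1, 0, 1, 0, 1, 0, 1, 0),
                       lab1 = seq_along(A),
                       lab2 = rev(seq_along(A))) {
  cohort_table(
    data.frame(A = A, B = B, lab1 = lab1, lab2 = lab2, readmitted = y),
    roles = c(A = "diagnosis", B = "diagnosis", lab1 = "lab_admission",
              lab2 = "lab_admission", readmitted = "outcome"))
}

## Linearly separable two-lab cohort (positives high on both labs).
separable_cohort <- function(n = 60, seed = 42) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  cohort_table(
    data.frame(D = rbinom(n, 1, 0.5),
               lab1 = rnorm(n, mean = ifelse(y == 1, 6, 0)),
               lab2 = rnorm(n, mean = ifelse(y == 1, 6, 0)),
               readmitted = y),
    roles = c(D = "diagnosis", lab1 = "lab_admission",
              lab2 = "lab_admission", readmitted = "outcome"))
}

## Moderate synthetic cohort with signal, small enough for fast fits.
small_signal_cohort <- function(n = 600, seed = 7, base_rate = 0.3) {
  generate_cohort(default_cohort_config(n, base_rate_target = base_rate,
                                        heterogeneity = 1, seed = seed))
}

## Fit a compact framework quickly: reduced family list keeps tests fast.
quick_fit <- function(tab, seed = 1, ...) {
  suppressWarnings(cades(
    tab,
    families = c("logistic_regression", "naive_bayes", "lda"),
    min_per_class = 10,
    seed = seed, ...))
}

## Exhaustive hypergeometric two-sided Fisher p (point-probability method),
## written independently of stats::fisher.test as an enumeration oracle.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  ## P(X = x) for hypergeometric via explicit log-factorials
  lfact <- function(x) lgamma(x + 1)
  logp <- function(x) {
    lfact(m) - lfact(x) - lfact(m - x) +
      lfact(n) - lfact(k - x) - lfact(n - (k - x)) -
      (lfact(m + n) - lfact(k) - lfact(m + n - k))
  }
  p_all <- exp(vapply(xs, logp, numeric(1)))
  p_obs <- p_all[xs == a]
  sum(p_all[p_all <= p_obs * (1 + 1e-07)])
}

## O(n^2) pair-counting AUROC oracle.
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

## Exact Mann-Whitney two-sided p by explicit enumeration of group
## assignments, counting U directly pair-by-pair (independent of midranks).
mw_oracle <- function(x, y) {
  pooled <- c(x, y); nx <- length(x); N <- length(pooled)
  u_of <- function(xs, ys) {
    tot <- 0
    for (a in xs) for (b in ys) tot <- tot + (a > b) + 0.5 * (a == b)
    tot
  }
  u_obs <- u_of(x, y)
  subsets <- utils::combn(N, nx)
  us <- apply(subsets, 2, function(s) u_of(pooled[s], pooled[-s]))
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

## A pool whose lone member always outputs probability 0.5 (predicting the
## positive class): an empty boosting committee. Used to pin down the
## balance-forced value of f6 and constant-classifier behaviour.
constant_pool <- function(feats) {
  rec <- list(family = "adaboost",
              model = list(stumps = list(), alphas = numeric(0)),
              kept = feats)
  structure(list(bases = list(list(index = 0L, family = "adaboost",
                                   rule = rule(), feature_names = feats,
                                   record = rec, n_train = 0L,
                                   class_counts = c(neg = 0L, pos = 0L))),
                 feature_names = feats),
            class = "cades_pool")
}

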