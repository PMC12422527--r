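## Continuous vs binary predictor split used by imputation and screening:
## labs are continuous; demographics are continuous unless their observed
## values are all 0/1; diagnosis columns are binary by construction.
continuous_cols <- function(table) {
  roles <- column_roles(table)
  cand <- names(roles)[roles %in% c("lab_admission", "lab_discharge", "demographic")]
  cand[vapply(cand, function(cn) {
    v <- table[[cn]][!is.na(table[[cn]])]
    length(v) == 0 || !all(v %in% c(0, 1))
  }, logical(1))]
}

binary_predictor_cols <- function(table) {
  setdiff(predictor_cols(table), continuous_cols(table))
}

#' Drop patients with too much missing data
#'
#' Removes rows whose fraction of missing predictor entries strictly exceeds
#' `max_fraction` (the outcome column is excluded from the fraction). Row
#' order of survivors is preserved.
#'
#' @param table a [cohort_table()].
#' @param max_fraction maximum tolerated missing fraction in \[0,1\]
#'   (default 0.10).
#' @return a filtered [cohort_table()]; warns (does not error) if no rows
#'   survive.
#' @export
filter_patients_by_missingness <- function(table, max_fraction = 0.10) {
  stopifnot(max_fraction >= 0, max_fraction <= 1)
  preds <- predictor_cols(table)
  frac <- rowMeans(is.na(as.data.frame(unclass(table))[preds]))
  keep <- frac <= max_fraction
  if (!any(keep)) warning("no patients survive the missingness filter")
  cohort_slice(table, which(keep))
}

#' k-nearest-neighbor imputation
#'
#' Distances between patients are Euclidean over z-scored continuous columns,
#' computed on mutually observed coordinates and rescaled by the fraction
#' observed (pairwise-complete metric). Each missing continuous cell is
#' replaced by the mean of the k nearest patients with that cell observed;
#' each missing binary cell by those neighbors' mode (ties to 0). Distance
#' ties break toward the lower row index. Idempotent on complete tables.
#'
#' With `donors` given, neighbors and standardization statistics come from
#' the donor table instead of `table` itself — use this to impute held-out
#' data from training data without leakage.
#'
#' @param table a [cohort_table()].
#' @param k number of neighbors (default 5); at most `nrow(table) - 1` (or
#'   `nrow(donors)` when donors are external).
#' @param donors optional [cohort_table()] with the same columns supplying
#'   neighbors; defaults to `table` itself (self-imputation, a row never
#'   being its own neighbor).
#' @return a complete [cohort_table()].
#' @export
knn_impute <- function(table, k = 5, donors = NULL) {
  self <- is.null(donors)
  if (self) donors <- table
  stopifnot(identical(names(table), names(donors)))
  stopifnot(k >= 1, k <= nrow(donors) - self)
  df <- as.data.frame(unclass(table), stringsAsFactors = FALSE)
  ddf <- as.data.frame(unclass(donors), stringsAsFactors = FALSE)
  preds <- predictor_cols(table)
  fully_missing <- preds[vapply(preds, function(cn) all(is.na(ddf[[cn]])),
                                logical(1))]
  if (length(fully_missing) > 0) {
    stop("column(s) fully missing: ", paste(fully_missing, collapse = ", "))
  }
  if (!anyNA(df[preds])) return(table)

  cont <- continuous_cols(table)
  bin <- binary_predictor_cols(table)
  Zd <- as.matrix(ddf[cont])
  mu <- colMeans(Zd, na.rm = TRUE)
  sdv <- apply(Zd, 2, stats::sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  zscore <- function(M) sweep(sweep(M, 2, mu), 2, sdv, "/")
  Zd <- zscore(Zd)
  Zt <- zscore(as.matrix(df[cont]))
  obs_d <- !is.na(Zd); Zd0 <- Zd; Zd0[!obs_d] <- 0
  obs_t <- !is.na(Zt); Zt0 <- Zt; Zt0[!obs_t] <- 0

  ## squared pairwise-complete distances, rescaled by fraction observed:
  ## d2[i,r] = (ncol / n_shared) * sum over shared cols of (z_i - z_r)^2
  d2 <- (Zt0^2) %*% t(obs_d) + obs_t %*% t(Zd0^2) - 2 * tcrossprod(Zt0, Zd0)
  d2[d2 < 0] <- 0
  shared <- tcrossprod(obs_t * 1, obs_d * 1)
  d2 <- ifelse(shared > 0, d2 * ncol(Zd) / shared, Inf)
  if (self) diag(d2) <- Inf

  need <- preds[colSums(is.na(df[preds])) > 0]
  for (cn in need) {
    miss_rows <- which(is.na(df[[cn]]))
    cand <- which(!is.na(ddf[[cn]]))
    for (i in miss_rows) {
      dd <- d2[i, cand]
      nb <- cand[order(dd, cand)][seq_len(min(k, length(cand)))]
      vals <- ddf[[cn]][nb]
      df[[cn]][i] <- if (cn %in% bin) {
        as.numeric(mean(vals) > 0.5)   # mode of 0/1 values, tie -> 0
      } else {
        mean(vals)
      }
    }
  }
  cohort_table(df, column_roles(table), attr(table, "patient_ids"))
}

#' Mann-Whitney U test
#'
#' `U` counts pairs where an `x` value exceeds a `y` value, ties counting
#' one half. The two-sided p-value is exact (full enumeration of group
#' assignments of the pooled sample, valid under ties) when
#' `length(x) + length(y) <= exact_limit`, and otherwise uses the normal
#' approximation with the tie-corrected variance.
#'
#' @param x,y non-empty numeric vectors.
#' @param exact_limit largest pooled size for exact enumeration (default 12).
#' @return list with `U` and `p_value`.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)                       # midranks
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (N <= exact_limit) {
    subsets <- utils::combn(N, nx)
    us <- colSums(matrix(r[subsets], nrow = nx)) - nx * (nx + 1) / 2
    p <- min(1, 2 * min(mean(us <= U + 1e-12), mean(us >= U - 1e-12)))
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- nx * ny / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(U = U, p_value = p)
}

#' Chi-square or Fisher exact test for a 2x2 table
#'
#' Applies the Fisher exact test (two-sided by the point-probability method,
#' as in [stats::fisher.test()]) when any expected count is below 5 or any
#' observed cell is zero, and otherwise the chi-square test with Yates
#' continuity correction. A zero row or column margin short-circuits to the
#' Fisher branch with p = 1.
#'
#' @param a,b,c,d cell counts: `a` = exposed cases, `b` = exposed controls,
#'   `c` = unexposed cases, `d` = unexposed controls.
#' @return list with `test` (`"chi_square"` or `"fisher_exact"`), `statistic`
#'   (`NA` for Fisher) and `p_value`.
#' @export
two_by_two_test <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  stopifnot(all(cnt >= 0), all(cnt == round(cnt)), sum(cnt) > 0)
  m <- matrix(cnt, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(test = "fisher_exact", statistic = NA_real_, p_value = 1))
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5) || any(m == 0)) {
    p <- stats::fisher.test(m)$p.value
    list(test = "fisher_exact", statistic = NA_real_, p_value = min(1, p))
  } else {
    ct <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    list(test = "chi_square", statistic = unname(ct$statistic),
         p_value = unname(ct$p.value))
  }
}

#' Univariate variable screening
#'
#' Two-step screening across the binary outcome: continuous predictors are
#' compared between outcome groups with the Mann-Whitney U test, binary
#' predictors with the chi-square or Fisher exact test ([two_by_two_test()]).
#' A variable is selected when its p-value is below `alpha`. Constant columns
#' get p = 1 and are never selected.
#'
#' @param table a complete (imputed) [cohort_table()].
#' @param alpha retention threshold (default 0.05).
#' @return a `data.frame` with columns `variable`, `test`, `statistic`,
#'   `p_value`, `selected` — one row per predictor.
#' @export
univariate_screen <- function(table, alpha = 0.05) {
  y <- outcome_values(table)
  cont <- continuous_cols(table)
  res <- lapply(predictor_cols(table), function(cn) {
    v <- table[[cn]]
    if (cn %in% cont) {
      if (length(unique(v)) == 1 || !all(c(0, 1) %in% y)) {
        out <- list(U = NA_real_, p_value = 1)
      } else {
        out <- mann_whitney_u(v[y == 1], v[y == 0])
      }
      data.frame(variable = cn, test = "mann_whitney",
                 statistic = out$U %||% NA_real_, p_value = out$p_value)
    } else {
      tt <- two_by_two_test(sum(v == 1 & y == 1), sum(v == 1 & y == 0),
                            sum(v == 0 & y == 1), sum(v == 0 & y == 0))
      data.frame(variable = cn, test = tt$test,
                 statistic = tt$statistic, p_value = tt$p_value)
    }
  })
  res <- do.call(rbind, res)
  res$selected <- res$p_value < alpha
  rownames(res) <- NULL
  res
}

#' MELD score
#'
#' Model for End-Stage Liver Disease:
#' `9.57 ln(creatinine) + 3.78 ln(bilirubin) + 11.20 ln(INR) + 6.43`, with
#' creatinine and bilirubin in mg/dL. Following the standard UNOS convention,
#' inputs below 1.0 are floored at 1.0 before taking logs so normal-range
#' values cannot contribute negative terms (set `floor_inputs = FALSE` for
#' the raw formula).
#'
#' @param creatinine_mg_dl,bilirubin_mg_dl,inr positive numerics (vectorized).
#' @param floor_inputs floor inputs at 1.0 before the log (default TRUE).
#' @return numeric MELD scores.
#' @examples
#' compute_meld(1, 1, 1)  # 6.43
#' @export
compute_meld <- function(creatinine_mg_dl, bilirubin_mg_dl, inr,
                         floor_inputs = TRUE) {
  if (any(creatinine_mg_dl <= 0) || any(bilirubin_mg_dl <= 0) || any(inr <= 0)) {
    stop("MELD inputs must be positive")
  }
  if (floor_inputs) {
    creatinine_mg_dl <- pmax(creatinine_mg_dl, 1)
    bilirubin_mg_dl <- pmax(bilirubin_mg_dl, 1)
    inr <- pmax(inr, 1)
  }
  9.57 * log(creatinine_mg_dl) + 3.78 * log(bilirubin_mg_dl) +
    11.20 * log(inr) + 6.43
}
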