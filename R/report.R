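#' Descriptive cohort characteristics by outcome group
#'
#' The standard clinical baseline table: binary variables as `n (%)` within
#' each outcome group with a chi-square / Fisher exact p-value, continuous
#' variables as `median (IQR)` with a Mann-Whitney U p-value. Percentages are
#' printed-style: half-up rounding to one decimal (see [pct()]).
#'
#' @param table a [cohort_table()].
#' @return data.frame with columns `variable`, `type`, `outcome_pos`,
#'   `outcome_neg` (formatted summaries), `test` and `p_value`.
#' @export
cohort_descriptives <- function(table) {
  y <- outcome_values(table)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  cont <- continuous_cols(table)
  fmt_pct <- function(count, total) {
    sprintf("%d (%.1f)", count, pct(count, total))
  }
  fmt_iqr <- function(v) {
    q <- stats::quantile(v, c(0.5, 0.25, 0.75), na.rm = TRUE, type = 7)
    sprintf("%.4g (%.4g-%.4g)", q[1], q[2], q[3])
  }
  rows <- lapply(predictor_cols(table), function(cn) {
    v <- table[[cn]]
    if (cn %in% cont) {
      mw <- if (all(c(0, 1) %in% y) && length(unique(v[!is.na(v)])) > 1) {
        mann_whitney_u(v[y == 1 & !is.na(v)], v[y == 0 & !is.na(v)])$p_value
      } else 1
      data.frame(variable = cn, type = "continuous",
                 outcome_pos = fmt_iqr(v[y == 1]),
                 outcome_neg = fmt_iqr(v[y == 0]),
                 test = "mann_whitney", p_value = mw)
    } else {
      a <- sum(v == 1 & y == 1, na.rm = TRUE)
      b <- sum(v == 1 & y == 0, na.rm = TRUE)
      tt <- two_by_two_test(a, b, n1 - a, n0 - b)
      data.frame(variable = cn, type = "binary",
                 outcome_pos = fmt_pct(a, n1),
                 outcome_neg = fmt_pct(b, n0),
                 test = tt$test, p_value = tt$p_value)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
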