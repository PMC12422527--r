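#' Conjunction rules over binary diagnosis columns
#'
#' A `rule` is a conjunction of literals `(column = TRUE/FALSE)` over the
#' diagnosis (complication/comorbidity) columns of a cohort, used to
#' characterize patient subgroups. Literals are kept in canonical form: unique
#' column names, sorted alphabetically. The empty rule is the vacuous
#' conjunction covering every row (used for pool members trained on the full
#' training set).
#'
#' @param literals named logical vector: names are diagnosis column names,
#'   values the required indicator value. May be empty.
#' @param support covered-row count, if known.
#' @return an object of class `cades_rule`.
#' @examples
#' rule(c(peritonitis = TRUE, gastritis = FALSE))
#' @export
rule <- function(literals = logical(0), support = NA_integer_) {
  stopifnot(is.logical(literals))
  if (length(literals) > 0) {
    if (is.null(names(literals)) || any(names(literals) == "") ||
        anyDuplicated(names(literals))) {
      stop("literals must have unique, non-empty names")
    }
    literals <- literals[order(names(literals))]
  }
  structure(list(literals = literals, support = as.integer(support)),
            class = "cades_rule")
}

is_full_rule <- function(r) length(r$literals) == 0L

#' Render / parse the rule text format
#'
#' Rules are serialized one per line as
#' `"(<name>=TRUE) AND (<name>=FALSE) support=<int>"`; the empty rule prints
#' as `TRUE`. `parse_rules()` reads this format back.
#'
#' @param x a `cades_rule`.
#' @param with_support append `support=<int>` when support is known.
#' @param ... unused.
#' @return `format.cades_rule()` a string; `parse_rules()` a list of rules.
#' @export
format.cades_rule <- function(x, with_support = FALSE, ...) {
  body <- if (is_full_rule(x)) "TRUE" else {
    paste(sprintf("(%s=%s)", names(x$literals),
                  ifelse(x$literals, "TRUE", "FALSE")),
          collapse = " AND ")
  }
  if (with_support && !is.na(x$support)) {
    body <- paste0(body, " support=", x$support)
  }
  body
}

#' @export
print.cades_rule <- function(x, ...) {
  cat(format(x, with_support = TRUE), "\n")
  invisible(x)
}

#' @param lines character vector, one rule per line.
#' @rdname format.cades_rule
#' @export
parse_rules <- function(lines) {
  lapply(lines, function(line) {
    line <- trimws(line)
    supp <- NA_integer_
    m <- regmatches(line, regexec("\\s+support=(\\d+)$", line))[[1]]
    if (length(m) == 2) {
      supp <- as.integer(m[2])
      line <- sub("\\s+support=\\d+$", "", line)
    }
    if (identical(line, "TRUE")) return(rule(support = supp))
    parts <- strsplit(line, " AND ", fixed = TRUE)[[1]]
    pieces <- lapply(parts, function(p) {
      mm <- regmatches(p, regexec("^\\((.+)=(TRUE|FALSE)\\)$", p))[[1]]
      if (length(mm) != 3) stop("cannot parse rule literal: ", p)
      mm
    })
    lits <- stats::setNames(vapply(pieces, function(mm) identical(mm[3], "TRUE"),
                                   logical(1), USE.NAMES = FALSE),
                            vapply(pieces, `[`, character(1), 2))
    rule(lits, supp)
  })
}

#' Rows of a cohort covered by a rule
#'
#' A row is covered when every literal is satisfied; a row with a missing
#' value in any rule column is not covered. The empty rule covers all rows.
#'
#' @param r a `cades_rule`.
#' @param table a [cohort_table()]; rule columns must be diagnosis-typed.
#' @return sorted integer vector of 1-based row indices.
#' @export
rule_coverage <- function(r, table) {
  if (is_full_rule(r)) return(seq_len(nrow(table)))
  dcols <- diagnosis_cols(table)
  unknown <- setdiff(names(r$literals), dcols)
  if (length(unknown) > 0) {
    stop("rule references non-diagnosis or unknown column(s): ",
         paste(unknown, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(table))
  for (cn in names(r$literals)) {
    v <- table[[cn]]
    keep <- keep & !is.na(v) & (v == as.numeric(r$literals[[cn]]))
  }
  which(keep)
}

#' Mine subgroup rules by exhaustive bounded-depth enumeration
#'
#' Enumerates every conjunction of 1 to `max_literals` literals over the
#' diagnosis columns, keeps rules with support at least `min_support` and at
#' least `min_per_class` covered rows of each outcome class, removes rules
#' whose coverage set duplicates another's (keeping the rule with fewest
#' literals, then the lexicographically smaller text), ranks by support
#' descending (ties broken lexicographically) and truncates to `max_rules`.
#' Exhaustiveness guarantees that any generative subgroup rule meeting the
#' support constraints is recovered.
#'
#' @param table a [cohort_table()] with at least one diagnosis column.
#' @param min_support minimum covered-row count.
#' @param max_literals maximum conjunction length (default 2, matching the
#'   two-literal complication patterns the framework targets).
#' @param min_per_class minimum covered rows of each outcome class (default
#'   20, enough to train a base classifier per class).
#' @param max_rules maximum number of rules returned (default 80).
#' @return list of `cades_rule`, support fields filled in.
#' @export
mine_rules <- function(table, min_support, max_literals = 2,
                       min_per_class = 20, max_rules = 80) {
  dcols <- sort(diagnosis_cols(table))
  if (length(dcols) == 0) stop("table has no diagnosis columns")
  stopifnot(min_support >= 1, max_literals >= 1, max_rules >= 1,
            min_per_class >= 0)
  y <- outcome_values(table)
  ## per-column satisfaction masks for both polarities
  mask <- list()
  for (cn in dcols) {
    v <- table[[cn]]
    mask[[paste0(cn, "=T")]] <- !is.na(v) & v == 1
    mask[[paste0(cn, "=F")]] <- !is.na(v) & v == 0
  }
  cand <- list()
  for (L in seq_len(min(max_literals, length(dcols)))) {
    for (cols in utils::combn(dcols, L, simplify = FALSE)) {
      grid <- expand.grid(rep(list(c(TRUE, FALSE)), L))
      for (g in seq_len(nrow(grid))) {
        lits <- stats::setNames(as.logical(grid[g, ]), cols)
        cov <- rep(TRUE, nrow(table))
        for (k in seq_len(L)) {
          cov <- cov & mask[[paste0(cols[k], if (lits[k]) "=T" else "=F")]]
        }
        supp <- sum(cov)
        if (supp < min_support) next
        if (min_per_class > 0) {
          n1 <- sum(y[cov] == 1)
          if (n1 < min_per_class || (supp - n1) < min_per_class) next
        }
        r <- rule(lits, supp)
        cand[[length(cand) + 1L]] <- list(rule = r, cov = which(cov))
      }
    }
  }
  if (length(cand) == 0) return(list())
  ## deduplicate identical coverage sets: fewest literals, then lexicographic
  keys <- vapply(cand, function(x) paste(x$cov, collapse = ","), character(1))
  texts <- vapply(cand, function(x) format(x$rule), character(1))
  nlits <- vapply(cand, function(x) length(x$rule$literals), integer(1))
  ord <- order(keys, nlits, texts)
  keep <- ord[!duplicated(keys[ord])]
  rules <- lapply(cand[keep], `[[`, "rule")
  supps <- vapply(rules, function(r) r$support, integer(1))
  texts <- vapply(rules, format, character(1))
  ord <- order(-supps, texts)
  rules <- rules[ord]
  rules[seq_len(min(max_rules, length(rules)))]
}
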