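#' Patient-by-variable cohort table
#'
#' A `cohort_table` is a `data.frame` of one row per admission episode with a
#' role attached to every column: binary diagnosis indicators (complications
#' and comorbidities), continuous laboratory values at admission or discharge,
#' demographics, and exactly one binary readmission outcome. Missing entries
#' are `NA`.
#'
#' @param data a data.frame; binary columns coded 0/1, continuous columns
#'   numeric.
#' @param roles named character vector mapping every column of `data` to one
#'   of `"diagnosis"`, `"lab_admission"`, `"lab_discharge"`, `"demographic"`,
#'   `"outcome"`.
#' @param patient_ids optional unique identifiers, one per row.
#' @return an object of class `cohort_table` (a data.frame with role and id
#'   attributes).
#' @export
cohort_table <- function(data, roles, patient_ids = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(names(roles)) || !setequal(names(roles), names(data))) {
    stop("`roles` must be a named vector covering exactly the columns of `data`")
  }
  roles <- roles[names(data)]
  ok <- roles %in% c("diagnosis", "lab_admission", "lab_discharge",
                     "demographic", "outcome")
  if (!all(ok)) stop("unknown role(s): ", paste(unique(roles[!ok]), collapse = ", "))
  out_cols <- names(roles)[roles == "outcome"]
  if (length(out_cols) != 1L) stop("exactly one outcome column is required")
  y <- data[[out_cols]]
  if (!all(y %in% c(0, 1) | is.na(y))) stop("outcome column must be binary 0/1")
  if (anyNA(y)) stop("outcome column must not contain missing values")
  for (cn in names(roles)[roles == "diagnosis"]) {
    v <- data[[cn]]
    if (!all(v %in% c(0, 1) | is.na(v))) {
      stop("diagnosis column '", cn, "' must contain only 0/1/NA")
    }
  }
  if (is.null(patient_ids)) patient_ids <- sprintf("P%06d", seq_len(nrow(data)))
  if (anyDuplicated(patient_ids)) stop("patient_ids must be unique")
  if (length(patient_ids) != nrow(data)) stop("one patient id per row required")
  structure(data,
            roles = roles,
            patient_ids = as.character(patient_ids),
            class = c("cohort_table", "data.frame"))
}

#' Column roles of a cohort table
#' @param x a `cohort_table`.
#' @return named character vector of roles.
#' @export
column_roles <- function(x) attr(x, "roles")

#' @export
print.cohort_table <- function(x, ...) {
  r <- column_roles(x)
  cat(sprintf("<cohort_table> %d patients x %d variables\n", nrow(x), ncol(x)))
  for (role in unique(r)) {
    cat(sprintf("  %-13s %s\n", paste0(role, ":"),
                paste(names(r)[r == role], collapse = ", ")))
  }
  invisible(x)
}

role_cols <- function(x, role) names(column_roles(x))[column_roles(x) %in% role]

#' Column names by role
#' @param x a `cohort_table`.
#' @name cohort-accessors
#' @return character vector of column names (or, for [outcome_values()], the
#'   0/1 outcome vector).
NULL

#' @rdname cohort-accessors
#' @export
diagnosis_cols <- function(x) role_cols(x, "diagnosis")

#' @rdname cohort-accessors
#' @export
lab_cols <- function(x) role_cols(x, c("lab_admission", "lab_discharge"))

#' @rdname cohort-accessors
#' @export
outcome_col <- function(x) role_cols(x, "outcome")

#' @rdname cohort-accessors
#' @export
predictor_cols <- function(x) setdiff(names(x), outcome_col(x))

#' @rdname cohort-accessors
#' @export
outcome_values <- function(x) x[[outcome_col(x)]]

#' Subset the rows of a cohort table
#'
#' @param x a `cohort_table`.
#' @param rows integer or logical row index.
#' @return a `cohort_table` with the selected rows, roles preserved.
#' @export
cohort_slice <- function(x, rows) {
  df <- as.data.frame(unclass(x), stringsAsFactors = FALSE)[rows, , drop = FALSE]
  rownames(df) <- NULL
  cohort_table(df, column_roles(x), attr(x, "patient_ids")[rows])
}

#' Write / read a cohort table as CSV plus a YAML schema sidecar
#'
#' The CSV holds one row per patient with a leading `patient_id` column;
#' missing entries are written as empty fields. Column roles are stored in a
#' YAML sidecar (`<path>.yaml`) so the table round-trips losslessly.
#'
#' @param x a `cohort_table`.
#' @param path CSV file path.
#' @param schema_path YAML sidecar path; defaults to `<path>.yaml`.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   a `cohort_table`.
#' @export
write_cohort <- function(x, path, schema_path = paste0(path, ".yaml")) {
  df <- cbind(patient_id = attr(x, "patient_ids"),
              as.data.frame(unclass(x), stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  yaml::write_yaml(list(columns = as.list(column_roles(x))), schema_path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, schema_path = paste0(path, ".yaml")) {
  schema <- yaml::read_yaml(schema_path)
  roles <- unlist(schema$columns)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  ids <- df$patient_id
  df$patient_id <- NULL
  cohort_table(df[names(roles)], roles, ids)
}
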