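#' Configuration for a synthetic cirrhosis-like cohort
#'
#' Describes a generative model for tabular admission-episode data: binary
#' diagnosis indicators with given prevalences, continuous labs (normal or
#' log-normal), demographics, latent patient subgroups defined by
#' first-match-wins conjunction rules over the diagnoses, and a
#' subgroup-specific logistic outcome model. A mandatory default subgroup
#' catches patients matching no rule, so subgroup assignment is always a
#' partition.
#'
#' @param n_patients number of rows to generate (at least 10).
#' @param diagnosis_specs named numeric vector of prevalences in \[0,1\], one
#'   per binary diagnosis column.
#' @param lab_specs list of lab descriptions, each a list with fields `name`,
#'   `dist` (`"normal"` or `"lognormal"`), `location`, `scale` (on the latent
#'   normal scale; log-normal labs exponentiate), and optional `shifts`, a
#'   numeric vector of additive latent-scale shifts, one per subgroup
#'   (including the default subgroup, last).
#' @param subgroup_rules list of [rule()] objects over diagnosis names; the
#'   default subgroup is implicit and always last. Assignment is
#'   first-match-wins in list order.
#' @param subgroup_coefficients list of length `length(subgroup_rules) + 1`;
#'   each element a list with `intercept` and `beta`, a named numeric vector
#'   over lab and/or diagnosis names. Lab coefficients act on the standardized
#'   latent lab value, diagnosis coefficients on the 0/1 indicator.
#' @param base_rate_target outcome prevalence to calibrate to, or `NULL` to
#'   use the intercepts as given.
#' @param demographic_specs list of demographic descriptions, each a list with
#'   `name`, `dist` (`"normal"` or `"bernoulli"`) and parameters (`location`,
#'   `scale` or `prob`).
#' @param missingness_rates named per-column missingness rates in \[0,1\]
#'   (used by [inject_missingness()]; generation itself is complete).
#' @param diag_correlation latent pairwise (tetrachoric-style) correlation
#'   between diagnosis indicators via a one-factor Gaussian copula; default 0
#'   (independent).
#' @param seed integer seed; generation is a pure function of the config.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          diagnosis_specs,
                          lab_specs = list(),
                          subgroup_rules = list(),
                          subgroup_coefficients,
                          base_rate_target = NULL,
                          demographic_specs = list(),
                          missingness_rates = numeric(0),
                          diag_correlation = 0,
                          seed = 1L) {
  if (n_patients < 10) stop("n_patients must be at least 10")
  stopifnot(all(diagnosis_specs >= 0 & diagnosis_specs <= 1),
            !is.null(names(diagnosis_specs)),
            diag_correlation >= 0, diag_correlation < 1)
  if (!is.null(base_rate_target)) {
    stopifnot(base_rate_target > 0, base_rate_target < 1)
  }
  if (length(missingness_rates) > 0) {
    stopifnot(all(missingness_rates >= 0 & missingness_rates <= 1))
  }
  n_sg <- length(subgroup_rules) + 1L
  if (length(subgroup_coefficients) != n_sg) {
    stop("need one coefficient set per subgroup rule plus one for the default subgroup")
  }
  lab_names <- vapply(lab_specs, `[[`, character(1), "name")
  for (r in subgroup_rules) {
    if (!inherits(r, "cades_rule")) stop("subgroup_rules must be cades_rule objects")
    bad <- setdiff(names(r$literals), names(diagnosis_specs))
    if (length(bad) > 0) {
      stop("subgroup rule references undeclared diagnosis column(s): ",
           paste(bad, collapse = ", "))
    }
  }
  for (sc in subgroup_coefficients) {
    vals <- c(sc$intercept, sc$beta)
    if (any(!is.finite(vals))) stop("subgroup coefficients must be finite")
    bad <- setdiff(names(sc$beta), c(lab_names, names(diagnosis_specs)))
    if (length(bad) > 0) {
      stop("coefficient references undeclared column(s): ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 diagnosis_specs = diagnosis_specs,
                 lab_specs = lab_specs,
                 subgroup_rules = subgroup_rules,
                 subgroup_coefficients = subgroup_coefficients,
                 base_rate_target = base_rate_target,
                 demographic_specs = demographic_specs,
                 missingness_rates = missingness_rates,
                 diag_correlation = diag_correlation,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

## First-match-wins subgroup assignment from a 0/1 diagnosis matrix.
assign_subgroups <- function(config, diag_df) {
  g <- rep.int(length(config$subgroup_rules) + 1L, nrow(diag_df))
  unassigned <- rep(TRUE, nrow(diag_df))
  for (k in seq_along(config$subgroup_rules)) {
    r <- config$subgroup_rules[[k]]
    sat <- rep(TRUE, nrow(diag_df))
    for (cn in names(r$literals)) {
      sat <- sat & !is.na(diag_df[[cn]]) &
        diag_df[[cn]] == as.numeric(r$literals[[cn]])
    }
    hit <- unassigned & sat
    g[hit] <- k
    unassigned <- unassigned & !hit
  }
  g
}

#' Generate a complete synthetic cohort
#'
#' Draws diagnoses, latent labs and demographics, assigns each patient to
#' exactly one generative subgroup (first matching rule wins, default catches
#' the rest), and draws the binary readmission outcome from that subgroup's
#' logistic model. When `base_rate_target` is set, a common intercept offset
#' is calibrated (monotone root-finding on the realized linear predictors) so
#' the expected outcome prevalence equals the target; the realized prevalence
#' is then within sampling error (about 3 percentage points for n >= 2000).
#' The result is complete (no missing values) and deterministic given
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return a [cohort_table()]; the outcome column is named `readmitted`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    prev <- config$diagnosis_specs
    d <- length(prev)

    ## diagnoses: one-factor Gaussian copula (rho = 0 -> independent)
    rho <- config$diag_correlation
    z_common <- stats::rnorm(n)
    diag_df <- as.data.frame(lapply(seq_len(d), function(j) {
      z <- sqrt(rho) * z_common + sqrt(1 - rho) * stats::rnorm(n)
      as.numeric(z < stats::qnorm(prev[j]))
    }))
    names(diag_df) <- names(prev)

    g <- assign_subgroups(config, diag_df)

    ## labs: latent standard normal + subgroup shift, mapped to natural scale
    lab_latent <- list()
    lab_df <- list()
    for (ls in config$lab_specs) {
      z <- stats::rnorm(n)
      shifts <- ls$shifts %||% rep(0, length(config$subgroup_coefficients))
      z <- z + shifts[g]
      lab_latent[[ls$name]] <- z
      val <- ls$location + ls$scale * z
      lab_df[[ls$name]] <- if (identical(ls$dist, "lognormal")) exp(val) else val
    }

    demo_df <- list()
    for (ds in config$demographic_specs) {
      demo_df[[ds$name]] <- switch(ds$dist,
        normal = stats::rnorm(n, ds$location, ds$scale),
        bernoulli = stats::rbinom(n, 1, ds$prob),
        stop("unknown demographic dist: ", ds$dist))
    }

    ## subgroup-specific linear predictor
    eta <- numeric(n)
    for (k in seq_along(config$subgroup_coefficients)) {
      rows <- which(g == k)
      if (length(rows) == 0) next
      sc <- config$subgroup_coefficients[[k]]
      e <- rep(sc$intercept %||% 0, length(rows))
      for (nm in names(sc$beta)) {
        xv <- if (nm %in% names(lab_latent)) lab_latent[[nm]][rows]
              else diag_df[[nm]][rows]
        e <- e + sc$beta[[nm]] * xv
      }
      eta[rows] <- e
    }

    if (!is.null(config$base_rate_target)) {
      f <- function(delta) mean(stats::plogis(eta + delta)) - config$base_rate_target
      delta <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
      eta <- eta + delta
    }
    y <- stats::rbinom(n, 1, stats::plogis(eta))

    df <- diag_df
    for (nm in names(lab_df)) df[[nm]] <- lab_df[[nm]]
    for (nm in names(demo_df)) df[[nm]] <- demo_df[[nm]]
    df$readmitted <- y
    lab_roles <- vapply(config$lab_specs, function(ls) {
      if (grepl("_discharge$", ls$name)) "lab_discharge" else "lab_admission"
    }, character(1))
    roles <- c(stats::setNames(rep("diagnosis", d), names(prev)),
               stats::setNames(lab_roles,
                               vapply(config$lab_specs, `[[`, character(1), "name")),
               stats::setNames(rep("demographic", length(demo_df)), names(demo_df)),
               readmitted = "outcome")
    cohort_table(df, roles)
  })
}

#' Generative subgroup labels for a generated cohort
#'
#' Recomputes the first-match-wins subgroup assignment from the table's
#' diagnosis columns under the config's rules. The default subgroup receives
#' the highest label.
#'
#' @param config the [cohort_config()] the table was generated from.
#' @param table the generated [cohort_table()].
#' @return integer vector of subgroup labels in `1..(n_rules + 1)`.
#' @export
ground_truth <- function(config, table) {
  stopifnot(inherits(config, "cohort_config"), inherits(table, "cohort_table"))
  if (!all(names(config$diagnosis_specs) %in% diagnosis_cols(table))) {
    stop("table does not carry the config's diagnosis columns")
  }
  if (nrow(table) != config$n_patients) {
    stop("table row count does not match config n_patients")
  }
  assign_subgroups(config, as.data.frame(unclass(table)))
}

#' Mask entries missing-completely-at-random
#'
#' Each entry of a column is set missing independently with that column's
#' rate. The outcome column must have rate 0.
#'
#' @param table a [cohort_table()].
#' @param rates named numeric vector of per-column rates in \[0,1\]; columns
#'   not named get rate 0.
#' @param seed integer seed.
#' @return a [cohort_table()] with injected `NA`s.
#' @export
inject_missingness <- function(table, rates, seed) {
  stopifnot(inherits(table, "cohort_table"),
            all(rates >= 0 & rates <= 1))
  oc <- outcome_col(table)
  if (oc %in% names(rates) && rates[[oc]] > 0) {
    stop("outcome column must have missingness rate 0")
  }
  with_seed(seed, {
    df <- as.data.frame(unclass(table), stringsAsFactors = FALSE)
    for (cn in names(rates)) {
      r <- rates[[cn]]
      if (r <= 0 || !cn %in% names(df) || cn == oc) next
      df[[cn]][stats::runif(nrow(df)) < r] <- NA
    }
    cohort_table(df, column_roles(table), attr(table, "patient_ids"))
  })
}

#' Default cirrhosis-like cohort template
#'
#' A ready-made [cohort_config()] mirroring the schema of a multicenter
#' decompensated-cirrhosis readmission cohort: six complications and four
#' comorbidities at realistic prevalences, fourteen labs (log-normal for
#' right-skewed analytes such as bilirubin and bile acids, normal otherwise,
#' including two discharge labs), age and sex, and three latent subgroups
#' (peritonitis; ruptured esophagogastric varices; default) whose outcome
#' models diverge by `heterogeneity`. At `heterogeneity = 0` all subgroups
#' share one logistic model; larger values make subgroup-specific effects
#' (including sign flips) stronger, so a single global model is increasingly
#' mis-specified.
#'
#' @param n_patients cohort size.
#' @param base_rate_target outcome prevalence; 0.128 emulates a 14-day
#'   readmission rate, 0.266 a 30-day rate.
#' @param heterogeneity non-negative scale on the divergence between subgroup
#'   coefficient vectors (default 1).
#' @param seed integer seed.
#' @return a [cohort_config()].
#' @export
default_cohort_config <- function(n_patients, base_rate_target = 0.128,
                                  heterogeneity = 1, seed = 1L) {
  prev <- c(peritonitis = 0.176, hepatic_encephalopathy = 0.077,
            abdominal_fluid = 0.087, liver_failure = 0.093,
            electrolyte_metabolic_disorder = 0.084,
            ruptured_esophagogastric_varices = 0.539,
            autoimmune_disease = 0.110, gastritis = 0.104,
            neuropathy = 0.029, ulcers = 0.098)
  lab <- function(name, dist, location, scale) {
    list(name = name, dist = dist, location = location, scale = scale)
  }
  labs <- list(
    lab("albumin", "normal", 31.5, 5.0),
    lab("erythrocyte_count", "normal", 3.3, 0.7),
    lab("leukocyte_count", "lognormal", log(3.9), 0.45),
    lab("hemoglobin", "normal", 99, 22),
    lab("platelets", "lognormal", log(65), 0.55),
    lab("total_bilirubin", "lognormal", log(26), 0.75),
    lab("inr", "lognormal", log(1.36), 0.18),
    lab("prothrombin_time", "normal", 16.7, 2.8),
    lab("creatinine", "lognormal", log(66), 0.30),
    lab("serum_sodium", "normal", 139, 3.6),
    lab("total_bile_acids", "lognormal", log(30), 0.9),
    lab("prealbumin", "lognormal", log(80), 0.55),
    lab("albumin_discharge", "normal", 32, 4.5),
    lab("total_bilirubin_discharge", "lognormal", log(24), 0.7)
  )
  rules <- list(rule(c(peritonitis = TRUE)),
                rule(c(ruptured_esophagogastric_varices = TRUE)))
  base_beta <- c(albumin = -0.5, total_bilirubin = 0.5, inr = 0.4,
                 serum_sodium = -0.3, creatinine = 0.3, liver_failure = 0.5)
  h <- heterogeneity
  add <- function(beta, extra) {
    for (nm in names(extra)) {
      beta[nm] <- (if (nm %in% names(beta)) beta[[nm]] else 0) + extra[[nm]]
    }
    beta
  }
  coefs <- list(
    list(intercept = 0, beta = add(base_beta, h * c(
      albumin = -0.8, total_bilirubin = 0.8, prothrombin_time = 0.6))),
    list(intercept = 0, beta = add(base_beta, h * c(
      albumin = 1.0, total_bilirubin = -0.8, hemoglobin = -0.7))),
    list(intercept = 0, beta = add(base_beta, h * c(
      inr = 0.8, serum_sodium = -0.7, prealbumin = -0.6)))
  )
  demo <- list(list(name = "age", dist = "normal", location = 55, scale = 12),
               list(name = "sex_male", dist = "bernoulli", prob = 0.661))
  lab_names <- vapply(labs, `[[`, character(1), "name")
  miss <- stats::setNames(rep(0.05, length(lab_names)), lab_names)
  cohort_config(n_patients = n_patients,
                diagnosis_specs = prev,
                lab_specs = labs,
                subgroup_rules = rules,
                subgroup_coefficients = coefs,
                base_rate_target = base_rate_target,
                demographic_specs = demo,
                missingness_rates = miss,
                seed = seed)
}

#' Null (no-signal) cohort template
#'
#' Same schema as [default_cohort_config()] but with every outcome
#' coefficient zero: the outcome is pure Bernoulli noise at the base rate and
#' no classifier can exceed chance discrimination.
#'
#' @inheritParams default_cohort_config
#' @return a [cohort_config()].
#' @export
null_cohort_config <- function(n_patients, base_rate_target = 0.128, seed = 1L) {
  cfg <- default_cohort_config(n_patients, base_rate_target,
                               heterogeneity = 0, seed = seed)
  cfg$subgroup_coefficients <- lapply(cfg$subgroup_coefficients, function(sc) {
    list(intercept = stats::qlogis(base_rate_target), beta = numeric(0))
  })
  cfg
}
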