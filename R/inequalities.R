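#' Demographic inequalities in register membership
#'
#' Multivariable binary logistic regression of CP register membership on
#' demographic factors, reported as adjusted odds ratios (aOR) with 95%
#' Wald confidence intervals, `exp(coef +/- 1.959964 * SE)`, from
#' observed-information standard errors. Missing ethnicity is retained as
#' its own `unknown` level; for the other covariates the default policy is
#' complete-case: rows with missing values are dropped and counted in the
#' missingness report. No multiple-testing adjustment is applied.
#'
#' @name inequalities
NULL

#' Declare the regression covariates
#'
#' The default specification: 10-year age bands (reference 18-29), sex
#' (reference male), local IMD quintiles (reference 1, least deprived),
#' grouped ethnicity with an `unknown` level (reference White), language
#' preference (reference English) and country of birth (reference UK).
#'
#' @return A `cp_regression_spec`: list of covariate declarations
#'   (`name`, `column`, `levels`, `ref`, `missing_policy`).
#' @export
regression_spec <- function() {
  spec <- list(
    list(name = "age_band", column = "age_band",
         levels = AGE_BAND_LABELS, ref = "18-29",
         missing_policy = "complete_case"),
    list(name = "sex", column = "sex",
         levels = c("male", "female"), ref = "male",
         missing_policy = "complete_case"),
    list(name = "imd_quintile", column = "imd_quintile",
         levels = as.character(1:5), ref = "1",
         missing_policy = "complete_case"),
    list(name = "ethnicity", column = "ethnicity_grouped",
         levels = ETHNICITY_LEVELS, ref = "White",
         missing_policy = "unknown_as_level"),
    list(name = "language", column = "language_preference",
         levels = c("English", "non-English"), ref = "English",
         missing_policy = "complete_case"),
    list(name = "country", column = "country_of_birth",
         levels = c("UK", "non-UK"), ref = "UK",
         missing_policy = "complete_case")
  )
  structure(spec, class = "cp_regression_spec")
}

#' Prepare the design data for the logistic model
#'
#' Aligns cohort and register on patient id, recodes each covariate as a
#' factor with its declared reference level first, applies the per-covariate
#' missing policy (`unknown_as_level` maps NA to the `unknown` level;
#' `complete_case` drops the row), and reports missingness per covariate.
#'
#' @param cohort Cohort tibble.
#' @param register CP register tibble from [build_cp_register()] (uses
#'   `on_register` as the outcome).
#' @param spec A `cp_regression_spec`.
#' @return List: `data` (factors plus logical `outcome`), `missingness`
#'   (tibble of missing counts per covariate), `n_used`,
#'   `n_dropped_missing`.
#' @export
prepare_design <- function(cohort, register, spec = regression_spec()) {
  df <- dplyr::inner_join(
    cohort, register[, c("patient_id", "on_register")], by = "patient_id"
  )
  n_total <- nrow(df)
  out <- tibble(outcome = df$on_register)
  missingness <- list()
  keep <- rep(TRUE, n_total)
  for (cv in spec) {
    x <- as.character(df[[cv$column]])
    n_missing <- sum(is.na(x))
    if (cv$missing_policy == "unknown_as_level") {
      x[is.na(x)] <- "unknown"
    } else {
      keep <- keep & !is.na(x)
    }
    bad <- setdiff(stats::na.omit(unique(x)), cv$levels)
    if (length(bad) > 0) {
      abort(paste0("covariate `", cv$name, "` has undeclared level(s): ",
                   paste(bad, collapse = ", ")))
    }
    out[[cv$name]] <- factor(x, levels = c(cv$ref, setdiff(cv$levels, cv$ref)))
    missingness[[cv$name]] <- tibble(
      covariate = cv$name, policy = cv$missing_policy, n_missing = n_missing
    )
  }
  out <- out[keep, , drop = FALSE]
  # unobserved levels cannot be estimated; drop them with a warning
  for (cv in spec) {
    unobserved <- setdiff(levels(out[[cv$name]]), unique(as.character(out[[cv$name]])))
    if (length(unobserved) > 0) {
      warn(paste0("covariate `", cv$name, "`: unobserved level(s) omitted: ",
                  paste(unobserved, collapse = ", ")))
      out[[cv$name]] <- droplevels(out[[cv$name]])
    }
  }
  if (length(unique(out$outcome)) < 2) {
    abort("outcome is constant after missing-data handling; cannot fit")
  }
  list(
    data = out,
    missingness = dplyr::bind_rows(missingness),
    n_used = nrow(out),
    n_dropped_missing = n_total - nrow(out)
  )
}

#' Fit the multivariable logistic model
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (`stats::glm`, binomial family, convergence tolerance 1e-10, up to 100
#' iterations). Errors on non-convergence, on perfectly collinear columns
#' (aliased coefficients), and on apparent separation (unbounded
#' coefficients); penalised alternatives are out of scope.
#'
#' @param design Output of [prepare_design()].
#' @return Tibble with one row per non-reference level: `variable`,
#'   `level`, `coefficient`, `se`, `aor`, `ci_lower`, `ci_upper`; with
#'   attributes `n_used` and `n_dropped_missing`.
#' @export
fit_logistic <- function(design) {
  fit <- stats::glm(
    outcome ~ ., family = stats::binomial(), data = design$data,
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)
  )
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    abort(paste0("perfectly collinear column(s) detected: ",
                 paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  if (max(abs(cf[-1])) > 15) {
    abort(paste0(
      "separation suspected (|coefficient| > 15 for ",
      names(cf)[-1][which.max(abs(cf[-1]))],
      "); a penalised fit would be needed and is out of scope"
    ))
  }
  if (!fit$converged) {
    abort(paste0("logistic fit did not converge in 100 iterations; ",
                 "deviance = ", signif(fit$deviance, 6)))
  }
  se <- sqrt(diag(stats::vcov(fit)))
  z <- 1.959964

  # map coefficient names back to (variable, level)
  covs <- setdiff(names(design$data), "outcome")
  rows <- purrr::map(covs, function(v) {
    lv <- levels(design$data[[v]])[-1] # non-reference
    tibble(variable = v, level = lv, term = paste0(v, lv))
  }) |> dplyr::bind_rows()
  stopifnot(all(rows$term %in% names(cf)))

  out <- rows |>
    dplyr::mutate(
      coefficient = unname(cf[.data$term]),
      se = unname(se[.data$term]),
      aor = exp(.data$coefficient),
      ci_lower = exp(.data$coefficient - z * .data$se),
      ci_upper = exp(.data$coefficient + z * .data$se)
    ) |>
    dplyr::select(-"term")
  attr(out, "n_used") <- design$n_used
  attr(out, "n_dropped_missing") <- design$n_dropped_missing
  out
}

#' Fit the inequalities model from cohort and register
#'
#' Convenience wrapper: [prepare_design()] then [fit_logistic()]; the
#' missingness report is attached as an attribute.
#'
#' @inheritParams prepare_design
#' @return The odds-ratio table of [fit_logistic()] with a `missingness`
#'   attribute.
#' @export
fit_inequalities <- function(cohort, register, spec = regression_spec()) {
  design <- prepare_design(cohort, register, spec)
  out <- fit_logistic(design)
  attr(out, "missingness") <- design$missingness
  out
}

#' Format the odds-ratio table for reporting
#'
#' One row per level in the declared order, reference rows labelled, aORs
#' and confidence bounds to 2 decimal places.
#'
#' @param table Odds-ratio table from [fit_logistic()].
#' @param spec The `cp_regression_spec` used for the fit.
#' @return Tibble with character columns `variable`, `level`,
#'   `adjusted_odds_ratio`, `ci_95`.
#' @export
odds_ratio_report <- function(table, spec = regression_spec()) {
  fmt <- function(x) sprintf("%.2f", round_half_up(x, 2))
  rows <- purrr::map(spec, function(cv) {
    fitted <- table[table$variable == cv$name, , drop = FALSE]
    ref_row <- tibble(
      variable = cv$name, level = cv$ref,
      adjusted_odds_ratio = "REFERENCE GROUP", ci_95 = ""
    )
    lvl_rows <- fitted |>
      dplyr::mutate(
        adjusted_odds_ratio = fmt(.data$aor),
        ci_95 = paste(fmt(.data$ci_lower), "to", fmt(.data$ci_upper))
      ) |>
      dplyr::select("variable", "level", "adjusted_odds_ratio", "ci_95")
    dplyr::bind_rows(ref_row, lvl_rows)
  })
  dplyr::bind_rows(rows)
}
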