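#' Cohort construction: eligibility and analysis covariates
#'
#' Applies the study eligibility rules — adults (18 or over at the
#' extraction date), a continuous registration covering the full 12 months
#' before extraction, and no informed-dissent flag — and derives the
#' analysis covariates: 10-year age bands, within-sample ("local") IMD
#' quintiles, and grouped ethnicity with missing ethnicity retained as its
#' own `unknown` level.
#'
#' @name cohort
NULL

AGE_BAND_LABELS <- c("18-29", "30-39", "40-49", "50-59",
                     "60-69", "70-79", "80-89", ">=90")
AGE_BAND_LOWER <- c(18L, 30L, 40L, 50L, 60L, 70L, 80L, 90L)

ETHNICITY_LEVELS <- c("White", "Black Caribbean", "Black African",
                      "Asian", "Mixed", "Other", "unknown")

# completed years at `at`
age_completed_years <- function(birth_date, at) {
  floor(lubridate::time_length(lubridate::interval(birth_date, at), "years"))
}

#' Age band for an age in completed years
#'
#' Closed 10-year bands from 18-29 up to 80-89, then an open-ended band for
#' 90 and over.
#'
#' @param age_years Integer vector of ages (>= 18).
#' @return Character vector of band labels.
#' @export
#' @examples
#' derive_age_bands(c(18, 29, 30, 60, 95))
derive_age_bands <- function(age_years) {
  idx <- findInterval(age_years, AGE_BAND_LOWER)
  out <- rep(NA_character_, length(age_years))
  ok <- !is.na(idx) & idx >= 1
  out[ok] <- AGE_BAND_LABELS[idx[ok]]
  out
}

#' Apply the study eligibility rules
#'
#' Retains patients aged 18 or over at `extraction_date`, with a
#' registration interval covering the whole 12 months (365 days) ending at
#' `extraction_date`, and with no informed-dissent flag. Each excluded
#' patient is counted under exactly one reason, checked in the order
#' `missing_birth_date`, `under_18`, `dissent`, `incomplete_record`, so
#' cohort size plus exclusions always equals the input size.
#'
#' @param patients Patients tibble (bundle schema).
#' @param extraction_date Extraction date.
#' @param window_days Length of the required continuous record (default 365).
#' @return List: `cohort` (eligible rows with `age_years`, `age_band`,
#'   `ethnicity_grouped` added) and `exclusions` (tibble of reason counts).
#' @export
apply_eligibility <- function(patients, extraction_date,
                              window_days = 365L) {
  assert_scalar_date(extraction_date, "extraction_date")
  age <- age_completed_years(patients$birth_date, extraction_date)
  reason <- dplyr::case_when(
    is.na(patients$birth_date) ~ "missing_birth_date",
    age < 18 ~ "under_18",
    patients$dissent ~ "dissent",
    patients$registration_start > extraction_date - window_days |
      patients$registration_end < extraction_date ~ "incomplete_record",
    TRUE ~ "eligible"
  )
  exclusions <- tibble(reason = reason[reason != "eligible"]) |>
    dplyr::count(.data$reason, name = "n_excluded")

  cohort <- patients[reason == "eligible", , drop = FALSE] |>
    dplyr::mutate(
      age_years = age[reason == "eligible"],
      age_band = derive_age_bands(.data$age_years),
      ethnicity_grouped = dplyr::if_else(
        is.na(.data$ethnicity_raw), "unknown", .data$ethnicity_raw
      )
    )
  unknown_eth <- setdiff(unique(cohort$ethnicity_grouped), ETHNICITY_LEVELS)
  if (length(unknown_eth) > 0) {
    warn(paste0("unrecognised ethnicity value(s) kept verbatim: ",
                paste(unknown_eth, collapse = ", ")))
  }
  list(cohort = cohort, exclusions = exclusions)
}

#' Assign within-sample IMD quintiles
#'
#' Quintile cut-points are the 20/40/60/80 percentiles of the IMD score
#' within the cohort itself ("local" quintiles), so the five groups are
#' equal-sized up to ties. Quintile 1 is least deprived (lowest scores).
#' A score equal to a cut-point — and hence any group of tied scores — is
#' assigned to the lower quintile, deterministically.
#'
#' @param cohort Cohort tibble with an `imd_score` column.
#' @return The cohort with an integer `imd_quintile` column (NA where the
#'   score is missing).
#' @export
#' @examples
#' ch <- tibble::tibble(imd_score = 1:10)
#' assign_imd_quintiles(ch)$imd_quintile
assign_imd_quintiles <- function(cohort) {
  scores <- cohort$imd_score
  observed <- scores[!is.na(scores)]
  if (length(observed) == 0) {
    warn("all IMD scores missing; quintiles set to NA")
    cohort$imd_quintile <- NA_integer_
    return(cohort)
  }
  if (length(observed) < 5) {
    warn("fewer than 5 IMD scores observed; quintiles are degenerate")
  }
  breaks <- stats::quantile(observed, probs = c(0.2, 0.4, 0.6, 0.8),
                            names = FALSE, type = 7)
  if (anyDuplicated(breaks) > 0) {
    warn("tied IMD quintile cut-points; tied groups assigned to the lower quintile")
  }
  q <- 1L + findInterval(scores, breaks, left.open = TRUE)
  q[is.na(scores)] <- NA_integer_
  cohort$imd_quintile <- as.integer(q)
  cohort
}

#' Build the full analysis cohort from a bundle
#'
#' Convenience wrapper: eligibility, then local IMD quintiles.
#'
#' @param bundle A `cp_bundle` (or any list with a `patients` tibble and an
#'   `extraction_date`).
#' @inheritParams apply_eligibility
#' @return List with `cohort` and `exclusions` as in [apply_eligibility()].
#' @export
build_cohort <- function(bundle, window_days = 365L) {
  elig <- apply_eligibility(bundle$patients, bundle$extraction_date,
                            window_days = window_days)
  elig$cohort <- assign_imd_quintiles(elig$cohort)
  elig
}
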