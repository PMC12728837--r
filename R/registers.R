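#' Chronic-pain register algorithm and comparator LTC registers
#'
#' The CP register admits a patient through either of two routes, or both:
#'
#' * **Medication criterion** — four or more prescription-only analgesic
#'   prescriptions in the 12 months before extraction. Tricyclics and
#'   antiepileptics count as analgesics only for patients *without* the
#'   corresponding dual-indication diagnosis (depression, epilepsy) at any
#'   date up to extraction. Multiple issues of the same code on the same
#'   day collapse to one.
#' * **Diagnostic criterion** — any tier-1 condition code at any date up to
#'   extraction; or any tier-2 condition code together with at least three
#'   counted analgesic prescriptions (same window and exclusions as the
#'   medication criterion). Cancer-pain codes never trigger.
#'
#' Diagnosis lookback is lifetime (any date up to extraction); only the
#' analgesic count is windowed to 12 months.
#'
#' Comparator long-term-condition registers are code-presence registers:
#' one or more codes from the LTC's code set at any date up to extraction.
#'
#' @name registers
NULL

#' Count analgesic prescriptions per patient
#'
#' Counts, for every cohort member, prescription events in the 12-month
#' window whose code is a prescription-only analgesic, after collapsing
#' same-day duplicates of the same code and removing events of a
#' dual-indication class when the patient carries a matching diagnosis at
#' any date up to extraction. Unknown medication codes are not counted and
#' are reported once per code.
#'
#' @param prescriptions Prescription events (`patient_id`, `date`,
#'   `medication_code`).
#' @param diagnoses Diagnosis events (`patient_id`, `date`,
#'   `condition_code`) used for the dual-indication exclusion.
#' @param codebook A `cp_codebook`.
#' @param extraction_date Extraction date; the window is the 365 days
#'   ending there.
#' @param patient_ids Patients to report (default: all with prescriptions).
#' @return Tibble `patient_id`, `analgesic_count` covering `patient_ids`.
#' @export
count_analgesic_prescriptions <- function(prescriptions, diagnoses, codebook,
                                          extraction_date,
                                          patient_ids = NULL) {
  stopifnot(inherits(codebook, "cp_codebook"))
  window <- analysis_window(extraction_date)
  counted <- counted_medications(codebook)

  unknown <- setdiff(unique(prescriptions$medication_code),
                     codebook$medications$medication_code)
  if (length(unknown) > 0) {
    inform(paste0("ignoring unknown medication code(s): ",
                  paste(unknown, collapse = ", ")))
  }

  nullified <- diagnoses |>
    dplyr::filter(.data$date <= extraction_date) |>
    dplyr::inner_join(dual_indication_rules(codebook), by = "condition_code") |>
    dplyr::distinct(.data$patient_id, .data$nullified_class)

  counts <- prescriptions |>
    dplyr::filter(in_window(.data$date, window)) |>
    dplyr::inner_join(
      counted[, c("medication_code", "analgesic_class")],
      by = "medication_code"
    ) |>
    dplyr::distinct(.data$patient_id, .data$date, .data$medication_code,
                    .keep_all = TRUE) |>
    dplyr::anti_join(
      nullified,
      by = c("patient_id", analgesic_class = "nullified_class")
    ) |>
    dplyr::count(.data$patient_id, name = "analgesic_count")

  ids <- patient_ids %||% unique(prescriptions$patient_id)
  tibble(patient_id = ids) |>
    dplyr::left_join(counts, by = "patient_id") |>
    dplyr::mutate(analgesic_count = dplyr::coalesce(.data$analgesic_count, 0L))
}

#' Medication criterion: four or more counted analgesics
#' @param analgesic_count Integer vector.
#' @return Logical vector.
#' @export
medication_criterion <- function(analgesic_count) {
  analgesic_count >= 4L
}

#' Diagnostic criterion with tier hierarchy
#'
#' Tier-1 codes trigger on their own; tier-2 codes trigger only with at
#' least three counted analgesics; cancer-pain codes never trigger.
#'
#' @param has_tier1,has_tier2 Logical vectors: any tier-1 / tier-2 code at
#'   any date up to extraction.
#' @param analgesic_count Counted analgesics in the 12-month window.
#' @return Tibble `diagnostic_criterion` (logical), `triggering_tier`
#'   (integer, NA when the criterion does not fire).
#' @export
diagnostic_criterion <- function(has_tier1, has_tier2, analgesic_count) {
  fires_1 <- has_tier1
  fires_2 <- !has_tier1 & has_tier2 & analgesic_count >= 3L
  tibble(
    diagnostic_criterion = fires_1 | fires_2,
    triggering_tier = dplyr::case_when(
      fires_1 ~ 1L, fires_2 ~ 2L, TRUE ~ NA_integer_
    )
  )
}

#' Build the chronic-pain register for a cohort
#'
#' Evaluates both criteria for every cohort member; the register is their
#' union. Events for patients outside the cohort are ignored (one summary
#' message). Patients with no events are off the register.
#'
#' @param cohort Cohort tibble (needs `patient_id`).
#' @param prescriptions,diagnoses Event tibbles.
#' @param codebook A `cp_codebook`.
#' @param extraction_date Extraction date.
#' @return Tibble with one row per cohort member: `patient_id`,
#'   `on_register`, `medication_criterion`, `diagnostic_criterion`,
#'   `analgesic_count`, `triggering_tier`.
#' @export
build_cp_register <- function(cohort, prescriptions, diagnoses, codebook,
                              extraction_date) {
  ids <- cohort$patient_id
  n_outside <- sum(!prescriptions$patient_id %in% ids) +
    sum(!diagnoses$patient_id %in% ids)
  if (n_outside > 0) {
    inform(paste0("ignoring ", n_outside, " event(s) for non-cohort patients"))
  }
  prescriptions <- dplyr::filter(prescriptions, .data$patient_id %in% ids)
  diagnoses <- dplyr::filter(diagnoses, .data$patient_id %in% ids)

  counts <- count_analgesic_prescriptions(
    prescriptions, diagnoses, codebook, extraction_date, patient_ids = ids
  )

  tiers <- diagnoses |>
    dplyr::filter(.data$date <= extraction_date) |>
    dplyr::mutate(
      tier = codebook$conditions$tier[
        match(.data$condition_code, codebook$conditions$condition_code)]
    ) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      has_tier1 = any(.data$tier == 1L, na.rm = TRUE),
      has_tier2 = any(.data$tier == 2L, na.rm = TRUE),
      .groups = "drop"
    )

  out <- counts |>
    dplyr::left_join(tiers, by = "patient_id") |>
    dplyr::mutate(
      has_tier1 = dplyr::coalesce(.data$has_tier1, FALSE),
      has_tier2 = dplyr::coalesce(.data$has_tier2, FALSE),
      medication_criterion = medication_criterion(.data$analgesic_count)
    )
  dc <- diagnostic_criterion(out$has_tier1, out$has_tier2,
                             out$analgesic_count)
  out$diagnostic_criterion <- dc$diagnostic_criterion
  out$triggering_tier <- dc$triggering_tier
  out$on_register <- out$medication_criterion | out$diagnostic_criterion
  out[, c("patient_id", "on_register", "medication_criterion",
          "diagnostic_criterion", "analgesic_count", "triggering_tier")]
}

#' Build a comparator LTC register
#'
#' Code-presence rule: a patient is on the register if they carry one or
#' more codes from the LTC's code set at any date up to extraction.
#'
#' @param cohort Cohort tibble.
#' @param diagnoses Diagnosis events.
#' @param codebook A `cp_codebook`.
#' @param ltc_name Name of a comparator LTC in the codebook.
#' @param extraction_date Extraction date.
#' @return Character vector of patient ids on the register.
#' @export
build_ltc_register <- function(cohort, diagnoses, codebook, ltc_name,
                               extraction_date) {
  defs <- codebook$ltc_definitions
  i <- match(ltc_name, defs$ltc_name)
  if (is.na(i)) {
    abort(paste0(
      "unknown LTC `", ltc_name, "`; available: ",
      paste(defs$ltc_name, collapse = ", ")
    ))
  }
  codes <- defs$condition_codes[[i]]
  hits <- diagnoses |>
    dplyr::filter(
      .data$date <= extraction_date,
      .data$condition_code %in% codes,
      .data$patient_id %in% cohort$patient_id
    )
  unique(hits$patient_id)
}

#' Build every register: CP plus all comparator LTCs
#'
#' @inheritParams build_cp_register
#' @return List: `cp` (the CP register tibble) and `ltc` (named list of
#'   patient-id vectors, one per comparator LTC).
#' @export
build_all_registers <- function(cohort, prescriptions, diagnoses, codebook,
                                extraction_date) {
  cp <- build_cp_register(cohort, prescriptions, diagnoses, codebook,
                          extraction_date)
  ltc_names <- codebook$ltc_definitions$ltc_name
  ltc <- lapply(ltc_names, function(nm) {
    build_ltc_register(cohort, diagnoses, codebook, nm, extraction_date)
  })
  names(ltc) <- ltc_names
  list(cp = cp, ltc = ltc)
}
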