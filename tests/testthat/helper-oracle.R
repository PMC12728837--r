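# Independent brute-force evaluation of the chronic-pain register rules,
# one patient at a time with plain loops. Deliberately shares no code with
# the vectorised implementation: it re-reads the rule from first principles
# (windowed counting of prescription-only analgesics with same-day
# same-code collapsing and dual-indication exclusion; lifetime tier lookup;
# 4+ medication threshold; tier-1 alone or tier-2 with 3+).
oracle_cp_register <- function(ids, prescriptions, diagnoses, codebook,
                               extraction_date) {
  meds <- as.data.frame(codebook$medications)
  conds <- as.data.frame(codebook$conditions)
  window_start <- extraction_date - 365

  res <- data.frame(patient_id = ids, on_register = FALSE,
                    medication_criterion = FALSE,
                    diagnostic_criterion = FALSE, analgesic_count = 0L,
                    triggering_tier = NA_integer_)
  for (j in seq_along(ids)) {
    id <- ids[j]
    rx <- prescriptions[prescriptions$patient_id == id &
                          prescriptions$date > window_start &
                          prescriptions$date <= extraction_date, ,
                        drop = FALSE]
    dx <- diagnoses[diagnoses$patient_id == id &
                      diagnoses$date <= extraction_date, , drop = FALSE]

    nullified_classes <- character()
    tier1 <- FALSE; tier2 <- FALSE
    for (code in dx$condition_code) {
      i <- which(conds$condition_code == code)
      if (length(i) == 0) next
      if (!is.na(conds$is_dual_indication_for[i])) {
        nullified_classes <- union(nullified_classes,
                                   conds$is_dual_indication_for[i])
      }
      if (!isTRUE(conds$is_cancer_pain[i]) && !is.na(conds$tier[i])) {
        if (conds$tier[i] == 1) tier1 <- TRUE
        if (conds$tier[i] == 2) tier2 <- TRUE
      }
    }

    seen <- character()
    count <- 0L
    for (r in seq_len(nrow(rx))) {
      i <- which(meds$medication_code == rx$medication_code[r])
      if (length(i) == 0) next
      if (!meds$prescription_only[i]) next
      if (meds$analgesic_class[i] == "non_analgesic") next
      if (meds$analgesic_class[i] %in% nullified_classes) next
      key <- paste(rx$medication_code[r], rx$date[r])
      if (key %in% seen) next
      seen <- c(seen, key)
      count <- count + 1L
    }

    med_crit <- count >= 4
    diag_crit <- FALSE; trig <- NA_integer_
    if (tier1) { diag_crit <- TRUE; trig <- 1L }
    else if (tier2 && count >= 3) { diag_crit <- TRUE; trig <- 2L }

    res$analgesic_count[j] <- count
    res$medication_criterion[j] <- med_crit
    res$diagnostic_criterion[j] <- diag_crit
    res$triggering_tier[j] <- trig
    res$on_register[j] <- med_crit || diag_crit
  }
  res
}

# a tiny hand-held bundle scaffold for unit tests
make_patients <- function(n, extraction = as.Date("2023-08-31"),
                          age = 50, dissent = FALSE, reg_years = 5) {
  tibble::tibble(
    patient_id = sprintf("X%03d", seq_len(n)),
    birth_date = extraction - round(age * 365.25) - 10,
    sex = rep(c("female", "male"), length.out = n),
    ethnicity_raw = "White",
    imd_score = seq_len(n),
    language_preference = "English",
    country_of_birth = "UK",
    registration_start = extraction - round(reg_years * 365.25),
    registration_end = extraction,
    dissent = dissent
  )
}

empty_events <- function(kind = c("prescriptions", "diagnoses")) {
  kind <- match.arg(kind)
  code_col <- if (kind == "prescriptions") "medication_code" else "condition_code"
  out <- tibble::tibble(patient_id = character(),
                        date = as.Date(character()))
  out[[code_col]] <- character()
  out
}
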