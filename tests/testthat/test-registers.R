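extraction <- as.Date("2023-08-31")
cb <- load_codebook()

rx <- function(id, dates, codes) {
  tibble::tibble(patient_id = id, date = as.Date(dates),
                 medication_code = codes)
}
dx <- function(id, dates, codes) {
  tibble::tibble(patient_id = id, date = as.Date(dates),
                 condition_code = codes)
}
count_one <- function(prescriptions, diagnoses = empty_events("diagnoses"),
                      id = "A") {
  out <- count_analgesic_prescriptions(prescriptions, diagnoses, cb,
                                       extraction, patient_ids = id)
  out$analgesic_count
}

test_that("analgesic counting: window, classes, dedup, dual indication", {
  days <- extraction - c(10, 40, 100, 300)
  # four opioid issues on distinct dates -> 4
  expect_identical(count_one(rx("A", days, "M010")), 4L)
  # four antiepileptic issues but an epilepsy code at any past date -> 0
  expect_identical(
    count_one(rx("A", days, "M040"),
              dx("A", extraction - 2000, "L015")),
    0L
  )
  # the same four issues with no epilepsy code count in full
  expect_identical(count_one(rx("A", days, "M040")), 4L)
  # tricyclics are nullified by a depression code
  expect_identical(
    count_one(rx("A", days, "M030"), dx("A", extraction - 30, "L003")),
    0L
  )
  # issues dated 13 months before extraction fall outside the window
  expect_identical(count_one(rx("A", extraction - 390 - 0:3, "M010")), 0L)
  # boundary: exactly 365 days before extraction is out, 364 is in
  expect_identical(count_one(rx("A", extraction - c(365, 364), "M010")), 1L)
  # same code, same day collapses to one; distinct codes same day do not
  expect_identical(
    count_one(rx("A", rep(extraction - 5, 3), c("M010", "M010", "M011"))),
    2L
  )
  # OTC analgesics and non-analgesic POMs never count
  expect_identical(
    count_one(rx("A", days, c("M003", "M022", "M060", "M061"))), 0L
  )
  # unknown codes are ignored with a message
  expect_message(
    n <- count_one(rx("A", days, c("M010", "ZZZ", "M010", "M011"))),
    "unknown medication code.*ZZZ"
  )
  expect_identical(n, 3L)
})

test_that("medication criterion threshold is four or more", {
  expect_identical(medication_criterion(c(0L, 3L, 4L, 9L)),
                   c(FALSE, FALSE, TRUE, TRUE))
})

test_that("diagnostic criterion follows the tier hierarchy", {
  # tier 1 with no analgesics fires; tier 2 needs three analgesics
  out <- diagnostic_criterion(
    has_tier1 = c(TRUE, FALSE, FALSE, FALSE),
    has_tier2 = c(FALSE, TRUE, TRUE, FALSE),
    analgesic_count = c(0L, 2L, 3L, 5L)
  )
  expect_identical(out$diagnostic_criterion, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(out$triggering_tier, c(1L, NA_integer_, 2L, NA_integer_))
})

test_that("cancer-pain codes never trigger the register", {
  cohort <- make_patients(1, extraction)
  reg <- build_cp_register(
    cohort, empty_events("prescriptions"),
    dx(cohort$patient_id, extraction - 50, "P090"), cb, extraction
  )
  expect_false(reg$on_register)
})

test_that("both criteria can fire for one patient", {
  cohort <- make_patients(1, extraction)
  id <- cohort$patient_id
  reg <- build_cp_register(
    cohort, rx(id, extraction - c(5, 15, 25, 35), "M012"),
    dx(id, extraction - 400, "P001"), cb, extraction
  )
  expect_true(reg$on_register)
  expect_true(reg$medication_criterion)
  expect_true(reg$diagnostic_criterion)
  expect_identical(reg$triggering_tier, 1L)
  expect_identical(reg$analgesic_count, 4L)
})

test_that("empty event tables put nobody on the register", {
  cohort <- make_patients(5, extraction)
  reg <- build_cp_register(cohort, empty_events("prescriptions"),
                           empty_events("diagnoses"), cb, extraction)
  expect_identical(nrow(reg), 5L)
  expect_false(any(reg$on_register))
})

test_that("events for non-cohort patients are ignored with a message", {
  cohort <- make_patients(2, extraction)
  presc <- rx("STRANGER", extraction - c(1, 2, 3, 4), "M010")
  expect_message(
    reg <- build_cp_register(cohort, presc, empty_events("diagnoses"),
                             cb, extraction),
    "non-cohort"
  )
  expect_false(any(reg$on_register))
})

test_that("pipeline register equals the brute-force oracle on synthetic bundles", {
  for (seed in c(101, 202, 303)) {
    b <- simulate_population(sim_config(n_patients = 400, seed = seed))
    el <- build_cohort(b)
    reg <- suppressMessages(build_cp_register(
      el$cohort, b$prescriptions, b$diagnoses, cb, b$extraction_date))
    oracle <- oracle_cp_register(el$cohort$patient_id, b$prescriptions,
                                 b$diagnoses, cb, b$extraction_date)
    expect_identical(reg$on_register, oracle$on_register)
    expect_identical(reg$medication_criterion, oracle$medication_criterion)
    expect_identical(reg$diagnostic_criterion, oracle$diagnostic_criterion)
    expect_identical(reg$analgesic_count, oracle$analgesic_count)
    expect_identical(reg$triggering_tier, oracle$triggering_tier)
  }
})

test_that("adding an analgesic prescription never removes anyone (monotonicity)", {
  b <- simulate_population(sim_config(n_patients = 400, seed = 42))
  el <- build_cohort(b)
  reg0 <- suppressMessages(build_cp_register(
    el$cohort, b$prescriptions, b$diagnoses, cb, b$extraction_date))
  extra <- tibble::tibble(
    patient_id = sample(el$cohort$patient_id, 100),
    date = b$extraction_date - 3, medication_code = "M013"
  )
  reg1 <- suppressMessages(build_cp_register(
    el$cohort, dplyr::bind_rows(b$prescriptions, extra), b$diagnoses,
    cb, b$extraction_date))
  expect_true(all(reg1$on_register[reg0$on_register]))
  expect_true(all(reg1$analgesic_count >= reg0$analgesic_count))
})

test_that("register size respects the union bound over the two criteria", {
  b <- simulate_population(sim_config(n_patients = 600, seed = 7))
  el <- build_cohort(b)
  reg <- suppressMessages(build_cp_register(
    el$cohort, b$prescriptions, b$diagnoses, cb, b$extraction_date))
  expect_gte(sum(reg$on_register),
             max(sum(reg$medication_criterion), sum(reg$diagnostic_criterion)))
  expect_identical(reg$on_register,
                   reg$medication_criterion | reg$diagnostic_criterion)
})

test_that("LTC registers are code-presence with lifetime lookback", {
  cohort <- make_patients(3, extraction)
  ids <- cohort$patient_id
  diagnoses <- dx(
    c(ids[1], ids[2], ids[3]),
    c(extraction - 3000, extraction - 1, extraction + 10),
    c("L001", "L002", "L001")
  )
  on_reg <- build_ltc_register(cohort, diagnoses, cb, "anxiety", extraction)
  # the post-extraction (corrupted) event for patient 3 is not counted
  expect_setequal(on_reg, ids[1:2])
  expect_error(
    build_ltc_register(cohort, diagnoses, cb, "gastritis", extraction),
    "unknown LTC.*available"
  )
})
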