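extraction <- as.Date("2023-08-31")

# design wrapper for hand-built 2x2 tables
design_2x2 <- function(n11, n10, n01, n00) {
  # exposed CP / exposed not / unexposed CP / unexposed not
  data <- tibble::tibble(
    outcome = rep(c(TRUE, FALSE, TRUE, FALSE), c(n11, n10, n01, n00)),
    exposure = factor(rep(c("yes", "yes", "no", "no"),
                          c(n11, n10, n01, n00)),
                      levels = c("no", "yes"))
  )
  list(data = data, n_used = nrow(data), n_dropped_missing = 0L)
}

test_that("univariable fits equal the closed-form cross-product odds ratio", {
  # balanced table: aOR exactly 1
  fit <- fit_logistic(design_2x2(10, 10, 10, 10))
  expect_equal(fit$aor, 1, tolerance = 1e-8)
  # 20/80 vs 10/90: cross-product (20*90)/(80*10) = 2.25
  fit <- fit_logistic(design_2x2(20, 80, 10, 90))
  expect_equal(fit$aor, 2.25, tolerance = 1e-6)
  expect_true(fit$ci_lower <= fit$aor && fit$aor <= fit$ci_upper)
  # a run of random tables against the closed form
  set.seed(99)
  for (i in 1:10) {
    n <- sample(20:60, 4, replace = TRUE)
    fit <- fit_logistic(design_2x2(n[1], n[2], n[3], n[4]))
    expect_equal(fit$aor, (n[1] * n[4]) / (n[2] * n[3]), tolerance = 1e-6)
  }
})

test_that("Wald intervals use exp(coef +/- 1.959964 se)", {
  fit <- fit_logistic(design_2x2(20, 80, 10, 90))
  expect_equal(fit$ci_lower, exp(fit$coefficient - 1.959964 * fit$se),
               tolerance = 1e-12)
  expect_equal(fit$ci_upper, exp(fit$coefficient + 1.959964 * fit$se),
               tolerance = 1e-12)
})

test_that("prepare_design applies per-covariate missing policies", {
  b <- simulate_population(sim_config(n_patients = 3000, seed = 21))
  el <- build_cohort(b)
  reg <- suppressMessages(build_cp_register(
    el$cohort, b$prescriptions, b$diagnoses, load_codebook(),
    b$extraction_date))
  design <- prepare_design(el$cohort, reg)
  # complete case on language/country: dropped rows are counted
  n_missing_cc <- sum(is.na(el$cohort$language_preference) |
                        is.na(el$cohort$country_of_birth))
  expect_identical(design$n_dropped_missing, n_missing_cc)
  expect_identical(design$n_used + design$n_dropped_missing, nrow(el$cohort))
  # ethnicity missing becomes the unknown level, not a dropped row
  expect_true("unknown" %in% levels(design$data$ethnicity))
  expect_false(anyNA(design$data$ethnicity))
  # ethnicity arriving as NA (not yet grouped) is counted but retained
  eth_na <- el$cohort
  eth_na$ethnicity_grouped[1:10] <- NA
  d2 <- prepare_design(eth_na, reg)
  rep_eth <- d2$missingness[d2$missingness$covariate == "ethnicity", ]
  expect_identical(rep_eth$policy, "unknown_as_level")
  expect_identical(rep_eth$n_missing, 10L)
  expect_identical(d2$n_dropped_missing, design$n_dropped_missing)
  # a fully observed cohort drops nobody
  full <- el$cohort
  full$language_preference <- "English"
  full$country_of_birth <- "UK"
  expect_identical(
    suppressWarnings(prepare_design(full, reg))$n_dropped_missing, 0L)
})

test_that("constant outcomes error; unobserved levels warn and are dropped", {
  cohort <- make_patients(20, extraction)
  cohort$age_years <- 50
  cohort$age_band <- "50-59"
  cohort$ethnicity_grouped <- "White"
  cohort$imd_quintile <- rep(1:5, 4)
  reg_const <- tibble::tibble(patient_id = cohort$patient_id,
                              on_register = rep(FALSE, 20))
  expect_error(suppressWarnings(prepare_design(cohort, reg_const)),
               "outcome is constant")
  reg_var <- tibble::tibble(patient_id = cohort$patient_id,
                            on_register = rep(c(TRUE, FALSE), 10))
  w <- testthat::capture_warnings(design <- prepare_design(cohort, reg_var))
  expect_true(any(grepl("unobserved level", w)))
  expect_false("18-29" %in% levels(design$data$age_band))
})

test_that("row order does not affect the coefficients", {
  b <- simulate_population(sim_config(n_patients = 4000, seed = 33))
  el <- build_cohort(b)
  reg <- suppressMessages(build_cp_register(
    el$cohort, b$prescriptions, b$diagnoses, load_codebook(),
    b$extraction_date))
  f1 <- suppressWarnings(fit_inequalities(el$cohort, reg))
  perm <- sample(nrow(el$cohort))
  f2 <- suppressWarnings(fit_inequalities(
    el$cohort[perm, ], reg[match(el$cohort$patient_id[perm],
                                 reg$patient_id), ]))
  expect_equal(f1$coefficient, f2$coefficient, tolerance = 1e-10)
})

test_that("under a planted null, about 5% of levels exclude 1", {
  # outcome independent of covariates: CI coverage calibration
  n_reps <- 25
  hits <- 0L; total <- 0L
  withr::with_seed(2024, {
    for (r in seq_len(n_reps)) {
      data <- tibble::tibble(
        outcome = stats::runif(2000) < 0.2,
        g1 = factor(sample(letters[1:4], 2000, replace = TRUE)),
        g2 = factor(sample(c("x", "y"), 2000, replace = TRUE))
      )
      fit <- fit_logistic(list(data = data, n_used = 2000,
                               n_dropped_missing = 0L))
      hits <- hits + sum(fit$ci_lower > 1 | fit$ci_upper < 1)
      total <- total + nrow(fit)
    }
  })
  expect_lt(abs(hits / total - 0.05), 0.05)
})

test_that("the report prints reference rows and two-decimal odds ratios", {
  b <- simulate_population(sim_config(n_patients = 4000, seed = 14))
  el <- build_cohort(b)
  reg <- suppressMessages(build_cp_register(
    el$cohort, b$prescriptions, b$diagnoses, load_codebook(),
    b$extraction_date))
  tab <- suppressWarnings(fit_inequalities(el$cohort, reg))
  orr <- odds_ratio_report(tab)
  expect_identical(orr$adjusted_odds_ratio[orr$level == "18-29"],
                   "REFERENCE GROUP")
  expect_identical(orr$adjusted_odds_ratio[1], "REFERENCE GROUP")
  fitted_rows <- orr$adjusted_odds_ratio != "REFERENCE GROUP"
  expect_true(all(grepl("^[0-9]+\\.[0-9]{2}$",
                        orr$adjusted_odds_ratio[fitted_rows])))
  expect_true(all(grepl("^[0-9.]+ to [0-9.]+$", orr$ci_95[fitted_rows])))
  # rows follow the declared covariate order
  expect_identical(unique(orr$variable),
                   c("age_band", "sex", "imd_quintile", "ethnicity",
                     "language", "country"))
})

test_that("separation and collinearity are reported as errors", {
  data <- tibble::tibble(
    outcome = rep(c(TRUE, FALSE), each = 50),
    g = factor(rep(c("a", "b"), each = 50))
  )
  expect_error(
    suppressWarnings(
      fit_logistic(list(data = data, n_used = 100, n_dropped_missing = 0L))),
    "separation"
  )
  data2 <- tibble::tibble(
    outcome = stats::runif(100) < 0.4,
    g1 = factor(rep(c("a", "b"), 50)),
    g2 = factor(rep(c("p", "q"), 50)) # perfectly collinear with g1
  )
  expect_error(
    fit_logistic(list(data = data2, n_used = 100, n_dropped_missing = 0L)),
    "collinear"
  )
})
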