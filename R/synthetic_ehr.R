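#' Synthetic primary-care EHR generator
#'
#' Generates seeded synthetic populations with the statistical structure the
#' downstream analyses assume: configurable demographic marginals, a latent
#' chronic-pain (CP) status drawn from a logistic model with planted odds
#' ratios, and conditional prescription / diagnosis / consultation event
#' streams. CP-positive patients receive events guaranteed to satisfy the
#' register rules of their assigned pathway; CP-negative patients receive
#' events guaranteed not to satisfy any rule (at most three counted
#' analgesics, at most two if a tier-2 code is present, and never a tier-1
#' code), so the generator truth is an exact oracle for the register
#' algorithm.
#'
#' @name synthetic_ehr
NULL

CRITERION_PATHWAYS <- c("medication_only", "tier1", "tier2", "both")

check_prob_map <- function(p, what) {
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    abort(paste0("`", what, "` must be a named probability vector"))
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort(paste0("`", what, "` probabilities must be nonnegative and sum to 1"))
  }
  invisible(p)
}

#' Build a simulation configuration
#'
#' All probability maps must sum to 1 (tolerance 1e-9). Defaults are the
#' "lambeth-like" preset: marginals of an inner-city, young, multi-ethnic,
#' deprived practice population; planted odds ratios with a dominant age
#' gradient; target register prevalence 18.6%; mean annual consultations
#' 15.3 for CP-positive patients and 6.7 overall.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer seed; the bundle is a deterministic function of
#'   (config, seed).
#' @param extraction_date Date the records are extracted; all events fall on
#'   or before it.
#' @param demographics Named list of probability maps: `sex`, `ethnicity`
#'   (including an `unknown` level), `language` / `country` (including a
#'   `missing` level, masked completely at random), `age_bands` over the
#'   eight 10-year bands.
#' @param cp_model List with `target_prevalence` and `odds_ratios` (named
#'   list per covariate of per-level odds ratios against the reference
#'   level). The intercept is calibrated at simulation time so the mean
#'   model probability over the drawn covariates equals `target_prevalence`.
#' @param criterion_mix Probabilities that a CP-positive patient is realised
#'   via the medication-only, tier-1-diagnosis, tier-2-plus-analgesics, or
#'   both (medication and tier-1) pathway.
#' @param utilisation List: `cp_mean` (annual consultations for CP-positive
#'   patients), `overall_mean` (whole population), `dispersion` (negative
#'   binomial size).
#' @param provider_mode_mix Probability map over the 12 `provider:mode`
#'   consultation cells.
#' @param ltc_prevalence Named vector of comparator-LTC prevalences (drawn
#'   independently of CP status).
#' @param near_miss_rate Probability a CP-negative patient carries a tier-2
#'   code (with at most two analgesics), exercising the tier logic
#'   negatively.
#' @param dual_script_rate Probability that a carrier of a dual-indication
#'   diagnosis (epilepsy, depression) also receives prescriptions of the
#'   nullified class, exercising the exclusion rule.
#' @param cancer_pain_rate Probability of carrying a cancer-pain code
#'   (which never triggers the register).
#' @param noise_script_rate Probability of receiving non-counted
#'   prescriptions (over-the-counter analgesics, non-analgesics).
#' @param dissent_rate Probability of an informed-dissent flag.
#' @param discontinuity_rate Probability the registration does not cover the
#'   full 12 months before extraction.
#' @param duration_missing_rate Fraction of consultations with no recorded
#'   duration.
#' @return A validated `cp_sim_config` list.
#' @export
sim_config <- function(
    n_patients,
    seed = 1L,
    extraction_date = as.Date("2023-08-31"),
    demographics = list(
      sex = c(female = 0.508, male = 0.492),
      ethnicity = c(
        "White" = 0.5400, "Black African" = 0.1015,
        "Black Caribbean" = 0.0637, "Asian" = 0.0812,
        "Mixed" = 0.0545, "Other" = 0.0821, "unknown" = 0.0770
      ),
      language = c(English = 0.5427, `non-English` = 0.2163, missing = 0.2410),
      country = c(UK = 0.2450, `non-UK` = 0.2970, missing = 0.4580),
      age_bands = c(
        "18-29" = 0.220, "30-39" = 0.260, "40-49" = 0.170, "50-59" = 0.130,
        "60-69" = 0.100, "70-79" = 0.070, "80-89" = 0.035, ">=90" = 0.015
      )
    ),
    cp_model = list(
      target_prevalence = 0.186,
      odds_ratios = list(
        age_band = c(
          "30-39" = 1.67, "40-49" = 3.07, "50-59" = 5.61, "60-69" = 9.32,
          "70-79" = 14.58, "80-89" = 27.73, ">=90" = 39.91
        ),
        sex = c(female = 2.22),
        imd_quintile = c("2" = 1.16, "3" = 1.28, "4" = 1.56, "5" = 1.70),
        ethnicity = c(
          "Black Caribbean" = 1.51, "Black African" = 1.49, "Asian" = 1.16,
          "Mixed" = 1.30, "Other" = 1.06, "unknown" = 0.87
        ),
        language = c("non-English" = 0.95),
        country = c("non-UK" = 0.61)
      )
    ),
    criterion_mix = c(medication_only = 0.35, tier1 = 0.30,
                      tier2 = 0.20, both = 0.15),
    utilisation = list(cp_mean = 15.3, overall_mean = 6.7, dispersion = 1.5),
    provider_mode_mix = c(
      "gp:face_to_face" = 0.40, "gp:telephone" = 0.25, "gp:home_visit" = 0.01,
      "gp:digital" = 0.09, "nurse:face_to_face" = 0.10,
      "nurse:telephone" = 0.03, "nurse:home_visit" = 0.005,
      "nurse:digital" = 0.005, "other_hcp:face_to_face" = 0.07,
      "other_hcp:telephone" = 0.03, "other_hcp:home_visit" = 0.005,
      "other_hcp:digital" = 0.005
    ),
    ltc_prevalence = c(
      anxiety = 0.214, depression = 0.150, hypertension = 0.120,
      asthma = 0.117, diabetes_mellitus = 0.085, chronic_kidney_disease = 0.060,
      hypothyroidism = 0.045, cancer = 0.045, coronary_heart_disease = 0.040,
      alcohol_dependence = 0.035, substance_misuse = 0.030, copd = 0.030,
      osteoporosis = 0.030, psoriasis = 0.030, atrial_fibrillation = 0.025,
      stroke_or_tia = 0.025, serious_mental_illness = 0.020,
      chronic_liver_disease = 0.020, glaucoma = 0.020, hiv = 0.015,
      heart_failure = 0.015, epilepsy = 0.012, dementia = 0.012,
      inflammatory_bowel_disease = 0.012, peripheral_arterial_disease = 0.010,
      heart_valve_disease = 0.010, learning_disability = 0.008,
      blindness_low_vision = 0.008, bronchiectasis = 0.006,
      parkinsons_disease = 0.004, multiple_sclerosis = 0.004
    ),
    near_miss_rate = 0.10,
    dual_script_rate = 0.50,
    cancer_pain_rate = 0.010,
    noise_script_rate = 0.30,
    dissent_rate = 0.026,
    discontinuity_rate = 0.087,
    duration_missing_rate = 0.30) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1) {
    abort("`n_patients` must be a single integer >= 1")
  }
  assert_scalar_date(extraction_date, "extraction_date")
  for (nm in names(demographics)) {
    check_prob_map(demographics[[nm]], paste0("demographics$", nm))
  }
  check_prob_map(criterion_mix, "criterion_mix")
  check_prob_map(provider_mode_mix, "provider_mode_mix")
  if (!setequal(names(criterion_mix), CRITERION_PATHWAYS)) {
    abort("criterion_mix must cover exactly the four register pathways")
  }
  if (length(provider_mode_mix) != 12) {
    abort("provider_mode_mix must cover the 12 provider:mode cells")
  }
  if (utilisation$dispersion <= 0) abort("utilisation$dispersion must be > 0")
  if (any(ltc_prevalence < 0 | ltc_prevalence > 1)) {
    abort("ltc_prevalence values must be probabilities")
  }
  tp <- cp_model$target_prevalence
  if (!is.numeric(tp) || tp <= 0 || tp >= 1) {
    abort("cp_model$target_prevalence must be in (0, 1)")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), seed = as.integer(seed),
      extraction_date = extraction_date, demographics = demographics,
      cp_model = cp_model, criterion_mix = criterion_mix,
      utilisation = utilisation, provider_mode_mix = provider_mode_mix,
      ltc_prevalence = ltc_prevalence, near_miss_rate = near_miss_rate,
      dual_script_rate = dual_script_rate, cancer_pain_rate = cancer_pain_rate,
      noise_script_rate = noise_script_rate, dissent_rate = dissent_rate,
      discontinuity_rate = discontinuity_rate,
      duration_missing_rate = duration_missing_rate
    ),
    class = "cp_sim_config"
  )
}

#' The "lambeth-like" preset configuration
#'
#' [sim_config()] with all defaults: the shipped calibration of an
#' inner-city practice population.
#'
#' @inheritParams sim_config
#' @return A `cp_sim_config`.
#' @export
lambeth_like_config <- function(n_patients, seed = 1L) {
  sim_config(n_patients = n_patients, seed = seed)
}

draw_categorical <- function(n, prob_map) {
  sample(names(prob_map), n, replace = TRUE, prob = unname(prob_map))
}

# linear predictor of the planted CP logit (excluding intercept)
planted_linear_predictor <- function(covariates, odds_ratios) {
  lp <- rep(0, nrow(covariates))
  for (cov in names(odds_ratios)) {
    or <- odds_ratios[[cov]]
    m <- unname(or[as.character(covariates[[cov]])])
    m[is.na(m)] <- 1 # reference or unlisted level
    lp <- lp + log(m)
  }
  lp
}

# Intercept such that the mean model probability over the realised
# covariates equals the target prevalence.
calibrate_intercept <- function(lp, target) {
  stats::uniroot(
    function(a) mean(stats::plogis(a + lp)) - target,
    interval = c(-30, 10), tol = 1e-10
  )$root
}

sample_distinct_day_offsets <- function(counts, n_days = 365L) {
  # one vector of day offsets (0-based, < n_days), distinct within patient
  unlist(lapply(counts[counts > 0], function(k) sample.int(n_days, k) - 1L),
         use.names = FALSE)
}

#' Simulate a synthetic population bundle
#'
#' Draws demographics, latent CP status, and conditional event streams. The
#' result is byte-identical across runs with the same configuration.
#'
#' @param config A `cp_sim_config` from [sim_config()].
#' @param codebook A `cp_codebook` supplying the vocabulary the events are
#'   coded in (default: the shipped codebook).
#' @return A `cp_bundle`: list with tibbles `patients`, `prescriptions`,
#'   `diagnoses`, `consultations`, `truth`, plus `extraction_date`.
#' @export
#' @examples
#' b <- simulate_population(sim_config(n_patients = 200, seed = 42))
#' nrow(b$patients)
simulate_population <- function(config, codebook = load_codebook()) {
  stopifnot(inherits(config, "cp_sim_config"), inherits(codebook, "cp_codebook"))
  withr::with_seed(config$seed, simulate_population_impl(config, codebook))
}

simulate_population_impl <- function(config, codebook) {
  n <- config$n_patients
  extraction <- config$extraction_date
  dem <- config$demographics
  patient_id <- sprintf("PT%07d", seq_len(n))

  ## ---- demographics --------------------------------------------------
  sex <- draw_categorical(n, dem$sex)
  ethnicity <- draw_categorical(n, dem$ethnicity)
  language_true <- draw_categorical(n, dem$language)
  country_true <- draw_categorical(n, dem$country)
  age_band <- draw_categorical(n, dem$age_bands)

  band_idx <- match(age_band, AGE_BAND_LABELS)
  lower <- AGE_BAND_LOWER[band_idx]
  upper <- c(AGE_BAND_LOWER[-1] - 1L, 105L)[band_idx]
  age_years <- lower + floor(stats::runif(n) * (upper - lower + 1))
  # birth date giving exactly `age_years` completed years at extraction
  birth_date <- extraction - lubridate::years(age_years) -
    lubridate::days(floor(stats::runif(n) * 364))

  imd_score <- round(stats::runif(n, 0, 50), 3)
  imd_quintile <- pmin(ceiling(imd_score / 10), 5L)
  imd_quintile[imd_quintile < 1L] <- 1L

  dissent <- stats::runif(n) < config$dissent_rate
  discontinuous <- stats::runif(n) < config$discontinuity_rate
  reg_start <- dplyr::if_else(
    discontinuous,
    extraction - floor(stats::runif(n, 30, 365)),
    extraction - 365L - floor(stats::runif(n, 0, 3650))
  )
  reg_end <- rep(extraction, n)

  ## ---- latent CP status ----------------------------------------------
  covars <- tibble(
    age_band = age_band, sex = sex,
    imd_quintile = as.character(imd_quintile), ethnicity = ethnicity,
    language = language_true, country = country_true
  )
  lp <- planted_linear_predictor(covars, config$cp_model$odds_ratios)
  alpha <- calibrate_intercept(lp, config$cp_model$target_prevalence)
  p_cp <- stats::plogis(alpha + lp)
  cp <- stats::runif(n) < p_cp

  pathway <- rep("none", n)
  pathway[cp] <- draw_categorical(sum(cp), config$criterion_mix)

  ## ---- diagnoses ------------------------------------------------------
  conds <- codebook$conditions
  tier1_codes <- conds$condition_code[!is.na(conds$tier) & conds$tier == 1L]
  tier2_codes <- conds$condition_code[!is.na(conds$tier) & conds$tier == 2L]
  cancer_codes <- conds$condition_code[conds$is_cancer_pain]

  random_past_date <- function(k, horizon_days = 5 * 365) {
    extraction - floor(stats::runif(k, 0, horizon_days))
  }
  dx <- list()

  # comparator LTC codes, independent of CP status
  for (i in seq_len(nrow(codebook$ltc_definitions))) {
    ltc_name <- codebook$ltc_definitions$ltc_name[i]
    prev <- config$ltc_prevalence[ltc_name]
    if (is.na(prev) || prev == 0) next
    carriers <- which(stats::runif(n) < prev)
    if (length(carriers) == 0) next
    codes <- codebook$ltc_definitions$condition_codes[[i]]
    dx[[length(dx) + 1]] <- tibble(
      patient_id = patient_id[carriers],
      date = random_past_date(length(carriers)),
      condition_code = sample(codes, length(carriers), replace = TRUE)
    )
  }

  # tiered pain codes by pathway; near-miss tier-2 codes for negatives
  t1 <- which(pathway %in% c("tier1", "both"))
  if (length(t1) > 0) {
    dx[[length(dx) + 1]] <- tibble(
      patient_id = patient_id[t1], date = random_past_date(length(t1)),
      condition_code = sample(tier1_codes, length(t1), replace = TRUE)
    )
  }
  t2 <- which(pathway == "tier2")
  near_miss <- which(!cp & stats::runif(n) < config$near_miss_rate)
  t2all <- c(t2, near_miss)
  if (length(t2all) > 0) {
    dx[[length(dx) + 1]] <- tibble(
      patient_id = patient_id[t2all], date = random_past_date(length(t2all)),
      condition_code = sample(tier2_codes, length(t2all), replace = TRUE)
    )
  }

  # cancer-pain codes never trigger; sprinkled across everyone
  cancer <- which(stats::runif(n) < config$cancer_pain_rate)
  if (length(cancer) > 0) {
    dx[[length(dx) + 1]] <- tibble(
      patient_id = patient_id[cancer], date = random_past_date(length(cancer)),
      condition_code = sample(cancer_codes, length(cancer), replace = TRUE)
    )
  }

  diagnoses <- dplyr::arrange(
    dplyr::bind_rows(dx), .data$patient_id, .data$date, .data$condition_code
  )

  ## ---- prescriptions --------------------------------------------------
  counted <- counted_medications(codebook)
  dual <- dual_indication_rules(codebook)
  nullified <- diagnoses |>
    dplyr::inner_join(dual, by = "condition_code") |>
    dplyr::distinct(.data$patient_id, .data$nullified_class)
  has_null <- function(class) {
    patient_id %in% nullified$patient_id[nullified$nullified_class == class]
  }
  no_ae <- has_null("antiepileptic")
  no_tca <- has_null("tricyclic")

  pool_all <- counted$medication_code
  pools <- list(
    both_ok = pool_all,
    no_ae = counted$medication_code[counted$analgesic_class != "antiepileptic"],
    no_tca = counted$medication_code[counted$analgesic_class != "tricyclic"],
    neither = counted$medication_code[
      !counted$analgesic_class %in% c("antiepileptic", "tricyclic")]
  )
  pool_key <- dplyr::case_when(
    no_ae & no_tca ~ "neither", no_ae ~ "no_ae",
    no_tca ~ "no_tca", TRUE ~ "both_ok"
  )

  # counted analgesic scripts per pathway (distinct days, so same-day
  # same-code collapsing cannot erode the guarantee)
  k <- integer(n)
  k[pathway %in% c("medication_only", "both")] <-
    4L + stats::rpois(sum(pathway %in% c("medication_only", "both")), 1.5)
  k[pathway == "tier1"] <-
    sample(0:3, sum(pathway == "tier1"), replace = TRUE,
           prob = c(0.50, 0.25, 0.15, 0.10))
  k[pathway == "tier2"] <- 3L
  neg <- which(!cp)
  k[neg] <- sample(0:3, length(neg), replace = TRUE,
                   prob = c(0.55, 0.20, 0.15, 0.10))
  k[near_miss] <- sample(0:2, length(near_miss), replace = TRUE,
                         prob = c(0.40, 0.35, 0.25))

  who <- rep(seq_len(n), k)
  offs <- sample_distinct_day_offsets(k)
  rx_counted <- tibble(
    patient_id = patient_id[who],
    date = extraction - offs,
    medication_code = unlist(
      lapply(which(k > 0), function(i) {
        sample(pools[[pool_key[i]]], k[i], replace = TRUE)
      }),
      use.names = FALSE
    )
  )

  # nullified-class scripts for dual-indication carriers (never counted)
  rx_dual <- purrr::map2(
    list(no_ae, no_tca), c("antiepileptic", "tricyclic"),
    function(flag, class) {
      rate <- if (class == "antiepileptic") config$dual_script_rate
              else config$dual_script_rate * 0.3
      idx <- which(flag & stats::runif(n) < rate)
      if (length(idx) == 0) return(NULL)
      kk <- 3L + stats::rpois(length(idx), 1.5)
      codes <- counted$medication_code[counted$analgesic_class == class]
      tibble(
        patient_id = rep(patient_id[idx], kk),
        date = extraction - floor(stats::runif(sum(kk), 0, 365)),
        medication_code = sample(codes, sum(kk), replace = TRUE)
      )
    }
  )

  # non-counted noise scripts: OTC analgesics and non-analgesics
  noise_codes <- codebook$medications$medication_code[
    !codebook$medications$prescription_only |
      codebook$medications$analgesic_class == "non_analgesic"
  ]
  noisy <- which(stats::runif(n) < config$noise_script_rate)
  rx_noise <- NULL
  if (length(noisy) > 0) {
    kk <- 1L + stats::rpois(length(noisy), 1)
    rx_noise <- tibble(
      patient_id = rep(patient_id[noisy], kk),
      date = extraction - floor(stats::runif(sum(kk), 0, 365)),
      medication_code = sample(noise_codes, sum(kk), replace = TRUE)
    )
  }

  prescriptions <- dplyr::arrange(
    dplyr::bind_rows(c(list(rx_counted), rx_dual, list(rx_noise))),
    .data$patient_id, .data$date, .data$medication_code
  )

  ## ---- consultations --------------------------------------------------
  util <- config$utilisation
  p_hat <- mean(cp)
  mu0 <- max((util$overall_mean - p_hat * util$cp_mean) / (1 - p_hat), 0.1)
  mu <- ifelse(cp, util$cp_mean, mu0)
  n_cons <- stats::rnbinom(n, size = util$dispersion, mu = mu)
  whoc <- rep(seq_len(n), n_cons)
  total <- length(whoc)
  cell <- draw_categorical(total, config$provider_mode_mix)
  provider <- sub(":.*$", "", cell)
  mode <- sub("^.*:", "", cell)
  sched <- codebook$cost_schedule
  cell_mean <- sched$mean_duration[
    match(paste(provider, mode, sep = ":"),
          paste(sched$provider, sched$mode, sep = ":"))
  ]
  duration <- pmax(1, round(cell_mean + stats::rnorm(total, 0, cell_mean / 4)))
  duration[stats::runif(total) < config$duration_missing_rate] <- NA_real_
  consultations <- tibble(
    patient_id = patient_id[whoc],
    date = extraction - floor(stats::runif(total, 0, 365)),
    provider = provider, mode = mode, duration = duration
  ) |>
    dplyr::arrange(.data$patient_id, .data$date, .data$provider, .data$mode)

  ## ---- assemble -------------------------------------------------------
  patients <- tibble(
    patient_id = patient_id, birth_date = birth_date, sex = sex,
    ethnicity_raw = dplyr::if_else(ethnicity == "unknown",
                                   NA_character_, ethnicity),
    imd_score = imd_score,
    language_preference = dplyr::if_else(language_true == "missing",
                                         NA_character_, language_true),
    country_of_birth = dplyr::if_else(country_true == "missing",
                                      NA_character_, country_true),
    registration_start = reg_start, registration_end = reg_end,
    dissent = dissent
  )
  truth <- tibble(patient_id = patient_id, cp_truth = cp, pathway = pathway)

  structure(
    list(patients = patients, prescriptions = prescriptions,
         diagnoses = diagnoses, consultations = consultations,
         truth = truth, extraction_date = extraction),
    class = "cp_bundle"
  )
}

#' @export
print.cp_bundle <- function(x, ...) {
  cat("<cp_bundle> extraction", format(x$extraction_date), "\n",
      " patients:      ", nrow(x$patients), "\n",
      " prescriptions: ", nrow(x$prescriptions), "\n",
      " diagnoses:     ", nrow(x$diagnoses), "\n",
      " consultations: ", nrow(x$consultations), "\n",
      " CP-positive:   ", sum(x$truth$cp_truth), "\n", sep = "")
  invisible(x)
}

bundle_files <- c(
  patients = "patients.csv", prescriptions = "prescriptions.csv",
  diagnoses = "diagnoses.csv", consultations = "consultations.csv",
  truth = "truth.csv"
)

#' Write a population bundle to a directory
#'
#' Emits five CSV files plus `meta.json` (the extraction date);
#' [read_bundle()] of the result reproduces the bundle.
#'
#' @param bundle A `cp_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cp_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(bundle_files)) {
    readr::write_csv(bundle[[nm]], file.path(dir, bundle_files[[nm]]))
  }
  jsonlite::write_json(
    list(extraction_date = format(bundle$extraction_date)),
    file.path(dir, "meta.json"), auto_unbox = TRUE
  )
  invisible(dir)
}

#' Read a population bundle from a directory
#'
#' Validates referential integrity (every event's patient exists) and the
#' temporal bound (no event after the extraction date) before returning.
#'
#' @param dir Directory written by [write_bundle()].
#' @return A `cp_bundle`.
#' @export
read_bundle <- function(dir) {
  for (f in c(bundle_files, "meta.json")) {
    if (!file.exists(file.path(dir, f))) {
      abort(paste0("bundle is missing file: ", f))
    }
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  extraction <- as.Date(meta$extraction_date)

  col_specs <- list(
    patients = readr::cols(
      patient_id = "c", birth_date = "D", sex = "c", ethnicity_raw = "c",
      imd_score = "d", language_preference = "c", country_of_birth = "c",
      registration_start = "D", registration_end = "D", dissent = "l"
    ),
    prescriptions = readr::cols(patient_id = "c", date = "D",
                                medication_code = "c"),
    diagnoses = readr::cols(patient_id = "c", date = "D",
                            condition_code = "c"),
    consultations = readr::cols(patient_id = "c", date = "D", provider = "c",
                                mode = "c", duration = "d"),
    truth = readr::cols(patient_id = "c", cp_truth = "l", pathway = "c")
  )
  tabs <- purrr::imap(bundle_files, function(f, nm) {
    readr::read_csv(file.path(dir, f), col_types = col_specs[[nm]],
                    progress = FALSE)
  })

  ids <- tabs$patients$patient_id
  for (nm in c("prescriptions", "diagnoses", "consultations")) {
    orphans <- setdiff(tabs[[nm]]$patient_id, ids)
    if (length(orphans) > 0) {
      abort(paste0(
        "referential-integrity error in ", bundle_files[[nm]],
        ": unknown patient id(s): ",
        paste(utils::head(orphans, 5), collapse = ", ")
      ))
    }
    if (nrow(tabs[[nm]]) > 0 && any(tabs[[nm]]$date > extraction)) {
      abort(paste0("events after extraction date in ", bundle_files[[nm]]))
    }
  }
  if (!setequal(tabs$truth$patient_id, ids)) {
    abort("truth.csv must cover exactly the patients in patients.csv")
  }

  structure(
    c(tabs, list(extraction_date = extraction)),
    class = "cp_bundle"
  )
}
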