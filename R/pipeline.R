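#' Pipeline orchestration and study-style reporting
#'
#' One entry point runs simulate -> cohort -> registers -> utilisation ->
#' cost -> inequalities from a single configuration, writing tidy CSVs
#' (prevalence, consultation-rate, and cost rankings; cost components; the
#' adjusted-odds-ratio table), a one-page text summary, a structured log
#' with row counts at every stage, and a run manifest (config hash, seed,
#' file digests) that fully determines a rerun.
#'
#' @name cli_reporting
NULL

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$n_patients) && is.null(config$bundle_dir)) {
    abort("config must provide either `n_patients` (simulate) or `bundle_dir`")
  }
  if (is.null(config$seed)) abort("config must provide `seed`")
  config$codebook <- config$codebook %||% default_codebook_path()
  config$use_recorded_duration <- isTRUE(config$use_recorded_duration)
  config
}

pipeline_stage <- function(name, log, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage `", name, "` failed: ",
                 conditionMessage(e)),
          parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' @param config A YAML file path or a list with at least `seed` and either
#'   `n_patients` (to simulate a population) or `bundle_dir` (to read an
#'   existing bundle); optional `codebook` (path) and
#'   `use_recorded_duration`.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage messages?
#' @return Invisibly, a list with every in-memory output plus the manifest.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  config <- read_pipeline_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character()
  log_add <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) inform(line)
  }

  codebook <- pipeline_stage("codebook", log_add, load_codebook(config$codebook))
  log_add("stage=codebook conditions=", nrow(codebook$conditions),
          " medications=", nrow(codebook$medications))

  bundle <- pipeline_stage("simulate", log_add, {
    if (!is.null(config$bundle_dir)) {
      read_bundle(config$bundle_dir)
    } else {
      simulate_population(
        sim_config(n_patients = config$n_patients,
                   seed = derive_seed(config$seed, "simulate")),
        codebook = codebook
      )
    }
  })
  log_add("stage=simulate patients=", nrow(bundle$patients),
          " prescriptions=", nrow(bundle$prescriptions),
          " diagnoses=", nrow(bundle$diagnoses),
          " consultations=", nrow(bundle$consultations))

  elig <- pipeline_stage("cohort", log_add, build_cohort(bundle))
  cohort <- elig$cohort
  log_add("stage=cohort eligible=", nrow(cohort),
          " excluded=", sum(elig$exclusions$n_excluded))

  registers <- pipeline_stage("registers", log_add, suppressMessages(
    build_all_registers(cohort, bundle$prescriptions, bundle$diagnoses,
                        codebook, bundle$extraction_date)
  ))
  cp_ids <- registers$cp$patient_id[registers$cp$on_register]
  log_add("stage=registers cp=", length(cp_ids),
          " ltc_registers=", length(registers$ltc))

  all_regs <- c(list(chronic_pain = cp_ids), registers$ltc)
  n_cohort <- nrow(cohort)

  prevalence <- tibble(
    ltc_name = names(all_regs),
    n_patients = vapply(all_regs, length, integer(1)),
    prevalence = vapply(all_regs, function(ids) {
      percent_of(length(ids), n_cohort)
    }, numeric(1))
  ) |> rank_conditions("prevalence")

  util_cost <- pipeline_stage("utilisation_costing", log_add, {
    rows <- purrr::imap(all_regs, function(ids, nm) {
      u <- suppressWarnings(consultation_rate(
        ids, bundle$consultations, bundle$extraction_date, nm))
      cst <- cost_summary(ids, bundle$consultations, codebook,
                          bundle$extraction_date, nm,
                          config$use_recorded_duration)
      comp <- stats::setNames(cst$components$cost_gbp, cst$components$provider)
      tibble(
        ltc_name = nm, n_patients = u$n_patients,
        total_consultations = u$total_consultations, mean_rate = u$mean_rate,
        total_cost_gbp = cst$total_cost_gbp,
        per_patient_cost_gbp = cst$per_patient_cost_gbp,
        gp_cost_gbp = comp[["gp"]], nurse_cost_gbp = comp[["nurse"]],
        other_hcp_cost_gbp = comp[["other_hcp"]]
      )
    })
    dplyr::bind_rows(rows)
  })
  utilisation_ranked <- rank_conditions(
    util_cost[, c("ltc_name", "n_patients", "total_consultations", "mean_rate")],
    "total_consultations"
  )
  cost_ranked <- rank_conditions(
    util_cost[, c("ltc_name", "n_patients", "total_cost_gbp",
                  "per_patient_cost_gbp", "gp_cost_gbp", "nurse_cost_gbp",
                  "other_hcp_cost_gbp")],
    "total_cost_gbp"
  )
  log_add("stage=utilisation_costing registers=", nrow(util_cost))

  ors <- pipeline_stage("inequalities", log_add, {
    fit_inequalities(cohort, registers$cp)
  })
  or_report <- odds_ratio_report(ors)
  log_add("stage=inequalities n_used=", attr(ors, "n_used"),
          " n_dropped_missing=", attr(ors, "n_dropped_missing"))

  outputs <- list(
    cohort = cohort, exclusions = elig$exclusions, cp_register = registers$cp,
    prevalence = prevalence, utilisation = utilisation_ranked,
    cost = cost_ranked, odds_ratios = ors, odds_ratio_report = or_report,
    missingness = attr(ors, "missingness")
  )

  files <- c(
    cohort = "cohort.csv", exclusions = "exclusions.csv",
    cp_register = "cp_register.csv", prevalence = "prevalence_ranking.csv",
    utilisation = "utilisation_ranking.csv", cost = "cost_ranking.csv",
    odds_ratios = "odds_ratios.csv",
    odds_ratio_report = "odds_ratio_report.csv",
    missingness = "missingness.csv"
  )
  for (nm in names(files)) {
    readr::write_csv(outputs[[nm]], file.path(out_dir, files[[nm]]))
  }
  writeLines(emit_summary(outputs), file.path(out_dir, "summary.txt"))
  writeLines(log_lines, file.path(out_dir, "log.txt"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("cpregister")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    extraction_date = format(bundle$extraction_date),
    row_counts = list(
      patients = nrow(bundle$patients), cohort = nrow(cohort),
      cp_register = length(cp_ids),
      consultations = nrow(bundle$consultations)
    ),
    output_digests = as.list(
      tools::md5sum(file.path(out_dir, unname(files)))
    )
  )
  names(manifest$output_digests) <- unname(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_add("stage=manifest written=", out_dir)

  invisible(c(outputs, list(manifest = manifest)))
}

#' One-page human-readable run summary
#'
#' @param outputs The output list of [run_pipeline()].
#' @param top Number of top-ranked conditions to show per table.
#' @return Character vector of report lines.
#' @export
emit_summary <- function(outputs, top = 5) {
  fmt_row <- function(...) sprintf(...)
  prev <- utils::head(outputs$prevalence, top)
  util <- utils::head(outputs$utilisation, top)
  cost <- utils::head(outputs$cost, top)
  n_cohort <- nrow(outputs$cohort)
  cp_prev <- outputs$prevalence$prevalence[
    outputs$prevalence$ltc_name == "chronic_pain"]
  ors <- outputs$odds_ratios
  top_ors <- utils::head(ors[order(-ors$aor), ], top)
  c(
    "Chronic-pain register: run summary",
    "==================================",
    fmt_row("Cohort size: %d", n_cohort),
    fmt_row("Chronic-pain register prevalence: %.1f%%", cp_prev),
    "",
    sprintf("Top %d conditions by prevalence (%%):", top),
    fmt_row("  %-28s %8.1f", prev$ltc_name, prev$prevalence),
    "",
    sprintf("Top %d conditions by total annual consultations:", top),
    fmt_row("  %-28s %8d (mean %.1f/patient/year)",
            util$ltc_name, util$total_consultations, util$mean_rate),
    "",
    sprintf("Top %d conditions by total annual consultation cost (GBP):", top),
    fmt_row("  %-28s %12.2f (%.0f/patient)",
            cost$ltc_name, cost$total_cost_gbp, cost$per_patient_cost_gbp),
    "",
    sprintf("Largest adjusted odds ratios for chronic pain (n used = %d):",
            attr(ors, "n_used") %||% NA_integer_),
    fmt_row("  %-12s %-16s %6.2f (%.2f to %.2f)",
            top_ors$variable, top_ors$level, top_ors$aor,
            top_ors$ci_lower, top_ors$ci_upper)
  )
}
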