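#' Consultation rates and costs per register
#'
#' Consultation summaries count *every* consultation of register members in
#' the 12-month window — overall utilisation, not pain-specific contacts.
#' Costs attach a unit cost to each consultation from its provider-by-mode
#' cell of the schedule (per-minute staff cost times mean consultation
#' duration), accumulated in integer pence so component costs sum exactly
#' to totals, and converted to GBP only at output. Reporting conventions:
#' rates to 1 decimal place, per-patient cost to the nearest pound, the
#' excess-cost headline to the nearest integer percent.
#'
#' @name utilisation_costing
NULL

#' Summarise annual consultation utilisation for a register
#'
#' @param register_ids Patient ids on the register.
#' @param consultations Consultation events (`patient_id`, `date`,
#'   `provider`, `mode`, `duration`).
#' @param extraction_date Extraction date; events are filtered to the 365
#'   days ending there.
#' @param ltc_name Label for the register.
#' @return List: `ltc_name`, `n_patients`, `total_consultations`,
#'   `mean_rate` (per patient per year, 1 dp), `breakdown` (tibble of
#'   counts per provider-mode cell).
#' @export
consultation_rate <- function(register_ids, consultations, extraction_date,
                              ltc_name = "register") {
  window <- analysis_window(extraction_date)
  n <- length(register_ids)
  events <- consultations |>
    dplyr::filter(.data$patient_id %in% register_ids,
                  in_window(.data$date, window))
  breakdown <- tidyr::expand_grid(provider = PROVIDERS, mode = MODES) |>
    dplyr::left_join(
      dplyr::count(events, .data$provider, .data$mode),
      by = c("provider", "mode")
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  total <- nrow(events)
  if (n == 0) {
    warn("empty register: mean consultation rate reported as 0")
    mean_rate <- 0
  } else {
    mean_rate <- rate_per_patient(total, n)
  }
  list(ltc_name = ltc_name, n_patients = n, total_consultations = total,
       mean_rate = mean_rate, breakdown = breakdown)
}

#' Attach a unit cost to each consultation
#'
#' Event cost is the `rate_per_minute * mean_duration` of its
#' provider-by-mode cell, in integer pence. With
#' `use_recorded_duration = TRUE`, an event's own recorded duration is
#' costed instead wherever it is present.
#'
#' @param consultations Consultation events.
#' @param codebook A `cp_codebook` carrying the cost schedule.
#' @param use_recorded_duration Cost recorded durations where available?
#' @return `consultations` with an integer `cost_pence` column.
#' @export
apply_cost_schedule <- function(consultations, codebook,
                                use_recorded_duration = FALSE) {
  stopifnot(inherits(codebook, "cp_codebook"))
  sched <- codebook$cost_schedule
  idx <- match(
    paste(consultations$provider, consultations$mode, sep = ":"),
    paste(sched$provider, sched$mode, sep = ":")
  )
  if (anyNA(idx) && nrow(consultations) > 0) {
    bad <- which(is.na(idx))[1]
    abort(paste0(
      "consultation with unknown provider/mode: ",
      consultations$provider[bad], "/", consultations$mode[bad],
      " (patient ", consultations$patient_id[bad], ")"
    ))
  }
  cost <- sched$cell_cost_pence[idx]
  if (use_recorded_duration) {
    rec <- !is.na(consultations$duration)
    cost[rec] <- as.integer(
      round(sched$rate_per_minute[idx[rec]] * 100 * consultations$duration[rec])
    )
  }
  consultations$cost_pence <- as.integer(cost)
  consultations
}

#' Summarise annual consultation costs for a register
#'
#' @inheritParams consultation_rate
#' @inheritParams apply_cost_schedule
#' @return List: `ltc_name`, `n_patients`, `total_cost_pence`,
#'   `total_cost_gbp`, `per_patient_cost_gbp` (nearest pound),
#'   `components` (tibble of exact pence and GBP totals per provider).
#' @export
cost_summary <- function(register_ids, consultations, codebook,
                         extraction_date, ltc_name = "register",
                         use_recorded_duration = FALSE) {
  window <- analysis_window(extraction_date)
  n <- length(register_ids)
  events <- consultations |>
    dplyr::filter(.data$patient_id %in% register_ids,
                  in_window(.data$date, window)) |>
    apply_cost_schedule(codebook, use_recorded_duration)
  components <- tibble(provider = PROVIDERS) |>
    dplyr::left_join(
      events |>
        dplyr::group_by(.data$provider) |>
        dplyr::summarise(cost_pence = sum(.data$cost_pence), .groups = "drop"),
      by = "provider"
    ) |>
    dplyr::mutate(
      cost_pence = dplyr::coalesce(.data$cost_pence, 0L),
      cost_gbp = .data$cost_pence / 100
    )
  total_pence <- sum(components$cost_pence)
  per_patient <- if (n > 0) round_half_up(total_pence / 100 / n, 0) else NA_real_
  list(
    ltc_name = ltc_name, n_patients = n,
    total_cost_pence = total_pence, total_cost_gbp = total_pence / 100,
    per_patient_cost_gbp = per_patient, components = components
  )
}

#' Excess per-patient cost of one register over another, in percent
#'
#' The headline comparison: `(a - b) / b * 100`, reported to the nearest
#' integer percent, computed on per-patient annual costs.
#'
#' @param a,b Cost summaries from [cost_summary()], or bare per-patient
#'   cost numbers.
#' @return Integer percent.
#' @export
#' @examples
#' excess_cost_percent(373, 289) # 29
excess_cost_percent <- function(a, b) {
  pp <- function(x) if (is.numeric(x)) x else x$per_patient_cost_gbp
  pa <- pp(a); pb <- pp(b)
  if (is.na(pb) || pb == 0) abort("comparator per-patient cost is zero or undefined")
  as.integer(round_half_up(100 * (pa - pb) / pb, 0))
}

#' Rank condition summaries by a metric
#'
#' Stable descending sort with ties broken alphabetically by `ltc_name`.
#'
#' @param summaries Tibble with a `ltc_name` column and the metric column.
#' @param metric One of the numeric columns of `summaries` (e.g.
#'   `"prevalence"`, `"total_consultations"`, `"total_cost_gbp"`).
#' @return `summaries` reordered, with a `rank` column.
#' @export
rank_conditions <- function(summaries, metric) {
  if (!metric %in% names(summaries)) {
    abort(paste0("unknown ranking metric `", metric, "`; available: ",
                 paste(setdiff(names(summaries), "ltc_name"), collapse = ", ")))
  }
  if (nrow(summaries) == 0) abort("at least one summary is required")
  out <- summaries[order(-summaries[[metric]], summaries$ltc_name), ]
  out$rank <- seq_len(nrow(out))
  out
}
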