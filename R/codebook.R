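#' Codebook: controlled vocabularies, tier hierarchy, and cost schedule
#'
#' The codebook bundles everything that parameterises the chronic-pain (CP)
#' register and the costing layer:
#'
#' * `medications` — one row per medication code, with its analgesic class
#'   (`simple_analgesic`, `opioid`, `nsaid`, `tricyclic`, `antiepileptic`,
#'   `other_analgesic`, `non_analgesic`) and whether it is prescription-only.
#'   Only prescription-only analgesics count toward the register's
#'   medication criterion.
#' * `conditions` — one row per condition code. A code is either *tiered*
#'   (tier 1 triggers the register on its own; tier 2 requires at least
#'   three analgesic prescriptions), a *cancer-pain* code (never triggers),
#'   or a comparator-LTC / diagnostic-context code. Context codes may carry
#'   `is_dual_indication_for`, naming the analgesic class they nullify
#'   (e.g. an epilepsy code nullifies antiepileptic counting).
#' * `ltc_definitions` — the comparator long-term-condition registers, each
#'   a named, non-empty set of condition codes.
#' * `cost_schedule` — all 12 provider-by-mode cells with a per-minute unit
#'   cost (GBP) and a mean consultation duration (minutes). The per-event
#'   cell cost is precomputed in integer pence.
#'
#' The shipped default codebook uses a synthetic vocabulary (the real
#' SNOMED-CT/EMIS lists are licensed and not redistributable) with the
#' documented shape: 33 tiered conditions of which 12 are tier 1, and 31
#' comparator LTCs.
#'
#' @name codebook
NULL

ANALGESIC_CLASSES <- c(
  "simple_analgesic", "opioid", "nsaid", "tricyclic",
  "antiepileptic", "other_analgesic"
)
MEDICATION_CLASSES <- c(ANALGESIC_CLASSES, "non_analgesic")
PROVIDERS <- c("gp", "nurse", "other_hcp")
MODES <- c("face_to_face", "telephone", "home_visit", "digital")

#' Path to the shipped default codebook
#' @return File path of the default codebook YAML.
#' @export
default_codebook_path <- function() {
  system.file("extdata", "default_codebook.yaml", package = "cpregister",
              mustWork = TRUE)
}

section_keys <- list(
  medications = list(
    required = c("medication_code", "analgesic_class", "prescription_only"),
    optional = "medication_name"
  ),
  conditions = list(
    required = c("condition_code", "condition_name"),
    optional = c("tier", "is_cancer_pain", "is_dual_indication_for", "ltc")
  ),
  cost_schedule = list(
    required = c("provider", "mode", "rate_per_minute", "mean_duration"),
    optional = character()
  )
)

parse_section <- function(raw, section) {
  keys <- section_keys[[section]]
  entries <- raw[[section]]
  if (is.null(entries) || length(entries) == 0) {
    abort(paste0("codebook section `", section, "` is missing or empty"))
  }
  rows <- purrr::imap(entries, function(e, i) {
    unknown <- setdiff(names(e), c(keys$required, keys$optional))
    if (length(unknown) > 0) {
      abort(paste0(
        "codebook `", section, "` entry ", i, " has unknown key(s): ",
        paste(unknown, collapse = ", ")
      ))
    }
    missing <- setdiff(keys$required, names(e))
    if (length(missing) > 0) {
      abort(paste0(
        "codebook `", section, "` entry ", i, " lacks required key(s): ",
        paste(missing, collapse = ", ")
      ))
    }
    for (k in keys$optional) e[[k]] <- e[[k]] %||% NA
    as_tibble(e[c(keys$required, keys$optional)])
  })
  dplyr::bind_rows(rows)
}

#' Load and validate a codebook
#'
#' Parses a YAML codebook with sections `medications`, `conditions` and
#' `cost_schedule` under a strict schema (unknown keys are rejected) and
#' checks all structural invariants: unique codes, known classes, tier in
#' \{1, 2\}, cancer-pain codes untiered, a code never both tiered and a
#' comparator-LTC/context code, non-empty LTC code sets, and a complete
#' 12-cell cost schedule with positive rates and durations.
#'
#' @param path Path to a codebook YAML file (default: the shipped codebook).
#' @return A `cp_codebook` object: a list with tibbles `medications`,
#'   `conditions`, `ltc_definitions`, `cost_schedule`.
#' @export
#' @examples
#' cb <- load_codebook()
#' sum(!is.na(cb$conditions$tier)) # 33 tiered conditions
load_codebook <- function(path = default_codebook_path()) {
  if (!file.exists(path)) abort(paste0("codebook file not found: ", path))
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(section_keys))
  if (length(unknown) > 0) {
    abort(paste0("codebook has unknown section(s): ",
                 paste(unknown, collapse = ", ")))
  }

  meds <- parse_section(raw, "medications")
  conds <- parse_section(raw, "conditions")
  sched <- parse_section(raw, "cost_schedule")

  # --- medications ---
  dup <- meds$medication_code[duplicated(meds$medication_code)]
  if (length(dup) > 0) {
    abort(paste0("duplicate medication_code in codebook: ",
                 paste(unique(dup), collapse = ", ")))
  }
  bad <- setdiff(meds$analgesic_class, MEDICATION_CLASSES)
  if (length(bad) > 0) {
    abort(paste0("unknown analgesic_class: ", paste(bad, collapse = ", ")))
  }
  if (!is.logical(meds$prescription_only)) {
    abort("medication `prescription_only` must be logical")
  }

  # --- conditions ---
  dup <- conds$condition_code[duplicated(conds$condition_code)]
  if (length(dup) > 0) {
    abort(paste0("duplicate condition_code in codebook: ",
                 paste(unique(dup), collapse = ", ")))
  }
  conds$tier <- as.integer(conds$tier)
  conds$is_cancer_pain <- !is.na(conds$is_cancer_pain) & conds$is_cancer_pain
  if (any(!is.na(conds$tier) & !conds$tier %in% c(1L, 2L))) {
    abort("condition tier must be 1 or 2 when present")
  }
  offending <- conds$condition_code[conds$is_cancer_pain & !is.na(conds$tier)]
  if (length(offending) > 0) {
    abort(paste0("cancer-pain codes must carry no tier: ",
                 paste(offending, collapse = ", ")))
  }
  offending <- conds$condition_code[!is.na(conds$tier) & !is.na(conds$ltc)]
  if (length(offending) > 0) {
    abort(paste0("a code cannot be both tiered and a comparator-LTC code: ",
                 paste(offending, collapse = ", ")))
  }
  bad <- setdiff(stats::na.omit(conds$is_dual_indication_for), ANALGESIC_CLASSES)
  if (length(bad) > 0) {
    abort(paste0("is_dual_indication_for must name an analgesic class, got: ",
                 paste(bad, collapse = ", ")))
  }

  ltc <- conds |>
    dplyr::filter(!is.na(.data$ltc)) |>
    dplyr::group_by(ltc_name = .data$ltc) |>
    dplyr::summarise(
      condition_codes = list(.data$condition_code), .groups = "drop"
    )

  # --- cost schedule ---
  sched$provider <- as.character(sched$provider)
  sched$mode <- as.character(sched$mode)
  want <- tidyr::expand_grid(provider = PROVIDERS, mode = MODES)
  have <- dplyr::distinct(sched, .data$provider, .data$mode)
  if (nrow(sched) != 12 || nrow(dplyr::inner_join(want, have,
      by = c("provider", "mode"))) != 12) {
    abort("cost_schedule must contain exactly the 12 provider x mode cells")
  }
  if (any(sched$rate_per_minute <= 0) || any(sched$mean_duration <= 0)) {
    abort("cost_schedule rates and durations must be positive")
  }
  sched$cell_cost_pence <-
    as.integer(round(sched$rate_per_minute * 100 * sched$mean_duration))

  structure(
    list(medications = meds, conditions = conds,
         ltc_definitions = ltc, cost_schedule = sched),
    class = "cp_codebook"
  )
}

#' Write a codebook back to YAML
#'
#' Inverse of [load_codebook()]: `load_codebook(write_codebook(cb, p))`
#' reproduces `cb` (comments and key order aside).
#'
#' @param codebook A `cp_codebook`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "cp_codebook"))
  drop_na_fields <- function(row) Filter(function(v) !is.na(v), row)
  tib_to_entries <- function(tb) {
    purrr::map(seq_len(nrow(tb)), function(i) drop_na_fields(as.list(tb[i, ])))
  }
  out <- list(
    medications = tib_to_entries(codebook$medications),
    conditions = tib_to_entries(codebook$conditions),
    cost_schedule = tib_to_entries(
      codebook$cost_schedule[, c("provider", "mode",
                                 "rate_per_minute", "mean_duration")]
    )
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.cp_codebook <- function(x, ...) {
  n_tiered <- sum(!is.na(x$conditions$tier))
  cat("<cp_codebook>\n",
      "  medications:   ", nrow(x$medications), "\n",
      "  conditions:    ", nrow(x$conditions),
      " (", n_tiered, " tiered, ",
      sum(x$conditions$tier == 1L, na.rm = TRUE), " tier 1)\n",
      "  comparator LTCs: ", nrow(x$ltc_definitions), "\n",
      "  cost schedule: ", nrow(x$cost_schedule), " cells\n", sep = "")
  invisible(x)
}

#' Resolve the tier of a condition code
#'
#' Returns 1 or 2 for tiered pain-associated conditions and `NA` otherwise:
#' cancer-pain codes, comparator-LTC and context codes, and codes absent
#' from the codebook (unknown codes are reported once each).
#'
#' @param condition_code Character vector of condition codes.
#' @param codebook A `cp_codebook`.
#' @return Integer vector of tiers (`NA` = does not participate in the
#'   tier hierarchy).
#' @export
resolve_tier <- function(condition_code, codebook) {
  stopifnot(inherits(codebook, "cp_codebook"))
  idx <- match(condition_code, codebook$conditions$condition_code)
  unknown <- unique(condition_code[is.na(idx)])
  if (length(unknown) > 0) {
    inform(paste0("resolve_tier: unknown condition code(s): ",
                  paste(unknown, collapse = ", ")))
  }
  codebook$conditions$tier[idx]
}

# Medication codes that count toward the CP criteria: prescription-only and
# in an analgesic class.
counted_medications <- function(codebook) {
  dplyr::filter(
    codebook$medications,
    .data$prescription_only, .data$analgesic_class != "non_analgesic"
  )
}

# condition_code -> analgesic class nullified for carriers of that code
dual_indication_rules <- function(codebook) {
  codebook$conditions |>
    dplyr::filter(!is.na(.data$is_dual_indication_for)) |>
    dplyr::select("condition_code", nullified_class = "is_dual_indication_for")
}
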