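#' Bundled PNOC009 trial tables
#'
#' The package ships the published per-patient demographics/outcome table
#' and the per-infusion distribution-volume table of the PNOC009
#' first-in-human CED trial (six patients, thirteen infusions) as plain
#' CSV fixtures, so the tabular analyses run without any external data.
#'
#' `pnoc009_patients()` returns one row per patient: `subject`, `sex`,
#' `age_years`, `total_ced_treatments`, `dose_level` (the string `"2-1"`
#' records an intra-patient de-escalation), `dlt`, `followup_months`
#' (from diagnosis), and `status` (`death` / `alive` / `lost`).
#'
#' `pnoc009_infusions()` returns one row per CED treatment: `subject`,
#' `ced_number`, gadoteridol concentration `gad_mM`, infusion volume
#' `vi_mL`, `duration_min`, baseline `tumor_cm3`, the per-treatment
#' distribution volume `vd_cm3`, and — on each subject's first row — the
#' per-patient union `total_vd_cm3`, `covered_cm3` and `coverage_pct`.
#'
#' @return A tibble (see Details).
#' @examples
#' pnoc009_patients()
#' dplyr::count(pnoc009_infusions(), subject)
#' @export
pnoc009_patients <- function() {
  path <- system.file("extdata", "pnoc009_table1.csv", package = "cedtrace",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject = "c", sex = "c", age_years = "d",
                    total_ced_treatments = "i", dose_level = "c",
                    dlt = "c", followup_months = "d", status = "c"))
}

#' @rdname pnoc009_patients
#' @export
pnoc009_infusions <- function() {
  path <- system.file("extdata", "pnoc009_table3.csv", package = "cedtrace",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject = "c", ced_number = "i", gad_mM = "d",
                    vi_mL = "d", duration_min = "d", tumor_cm3 = "d",
                    vd_cm3 = "d", total_vd_cm3 = "d", covered_cm3 = "d",
                    coverage_pct = "d"))
}

#' Cycle-1 toxicity history of the PNOC009 cohort
#'
#' Reconstructs, as [cycle_outcome()] rows, the first-cycle toxicity
#' narrative that drove the escalation decisions: patient 1 treated at
#' dose level 1 with only unrelated toxicity; patient 2 at dose level 2
#' with several related grade 2 adverse events (the second of which
#' triggered the transition from accelerated titration to 3+3); patient
#' 3 with a surgery-related grade 3 muscle weakness (the trial's one
#' DLT, prompting intra-patient de-escalation); patients 4-6 at dose
#' level 2 with at most tolerable grade <= 2 related toxicity.
#'
#' @return Tibble of cycle-1 outcomes, one row per patient, suitable for
#'   [replay_history()].
#' @export
pnoc009_history <- function() {
  dplyr::bind_rows(
    cycle_outcome("PNOC009-1", cycle = 1, dose_level = 1, max_related_grade = 0),
    cycle_outcome("PNOC009-2", cycle = 1, dose_level = 2, max_related_grade = 2,
                  tolerable_grade2 = TRUE, n_related_grade2plus = 2),
    cycle_outcome("PNOC009-3", cycle = 1, dose_level = 2, max_related_grade = 3,
                  neurological = TRUE, related = TRUE),
    cycle_outcome("PNOC009-4", cycle = 1, dose_level = 2, max_related_grade = 1),
    cycle_outcome("PNOC009-5", cycle = 1, dose_level = 2, max_related_grade = 2,
                  tolerable_grade2 = TRUE),
    cycle_outcome("PNOC009-6", cycle = 1, dose_level = 2, max_related_grade = 2,
                  tolerable_grade2 = TRUE)
  )
}
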