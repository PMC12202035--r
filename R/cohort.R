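#' Specification of a synthetic trial cohort
#'
#' Parameters of the cohort-level simulator: per-dose-level toxicity
#' probabilities, exponential overall-survival with a given median, and
#' a Bernoulli lost-to-follow-up mechanism. Defaults mirror a small
#' first-in-human CED cohort: median OS 14.3 months, one patient in six
#' lost to follow-up, and up to 5 treatment cycles per patient.
#'
#' @param n_patients Number of patients.
#' @param dlt_prob_per_dose Probability of a cycle dose-limiting toxicity
#'   at each dose level.
#' @param grade2_prob_per_dose Probability of a (tolerable, related)
#'   grade 2 toxicity at each dose level, given no DLT.
#' @param survival_median_months Median of the exponential OS
#'   distribution (months from diagnosis).
#' @param lost_prob Probability a patient is lost to follow-up before
#'   death or study end.
#' @param followup_cutoff_months Administrative censoring horizon:
#'   patients alive past this time are recorded `alive` at the cutoff.
#' @param max_cycles Number of treatment cycles simulated per patient.
#' @param seed Integer RNG seed.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 6L,
                        dlt_prob_per_dose = c(0.05, 0.15),
                        grade2_prob_per_dose = c(0.15, 0.30),
                        survival_median_months = 14.3,
                        lost_prob = 1 / 6,
                        followup_cutoff_months = 72,
                        max_cycles = 5L,
                        seed = 1L) {
  if (length(dlt_prob_per_dose) != length(grade2_prob_per_dose)) {
    abort("cohort_spec: probability vectors must have one entry per dose level")
  }
  stopifnot(n_patients >= 1, all(dlt_prob_per_dose >= 0 & dlt_prob_per_dose <= 1),
            all(grade2_prob_per_dose >= 0 & grade2_prob_per_dose <= 1),
            survival_median_months > 0, lost_prob >= 0, lost_prob <= 1,
            followup_cutoff_months > 0, max_cycles >= 1)
  structure(list(
    n_patients = as.integer(n_patients),
    dlt_prob_per_dose = dlt_prob_per_dose,
    grade2_prob_per_dose = grade2_prob_per_dose,
    survival_median_months = survival_median_months,
    lost_prob = lost_prob,
    followup_cutoff_months = followup_cutoff_months,
    max_cycles = as.integer(max_cycles),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Simulate a trial cohort: survival records and per-cycle toxicity
#'
#' Survival times are exponential with the configured median
#' (`rate = log(2) / median`). A fraction `lost_prob` of patients is lost
#' to follow-up at a uniform fraction of their (unobserved) death time;
#' patients surviving past the follow-up cutoff are recorded alive.
#' Toxicity outcomes are drawn per patient, cycle and dose level, so the
#' same cohort can be replayed under any escalation path.
#'
#' @param spec A [cohort_spec()].
#' @return List with two tibbles: `survival` (`subject_id`,
#'   `time_months`, `status` in death/alive/lost) and `toxicity`
#'   (`subject_id`, `cycle`, `dose_level`, `dlt`, `grade2`).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 4, seed = 2))
#' cohort$survival
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(spec$seed)

  n <- spec$n_patients
  ids <- sprintf("SYN-%03d", seq_len(n))
  death_time <- rexp(n, rate = log(2) / spec$survival_median_months)
  lost <- runif(n) < spec$lost_prob
  lost_time <- runif(n) * death_time

  status <- dplyr::case_when(
    lost ~ "lost",
    death_time > spec$followup_cutoff_months ~ "alive",
    TRUE ~ "death"
  )
  time <- dplyr::case_when(
    lost ~ lost_time,
    death_time > spec$followup_cutoff_months ~ spec$followup_cutoff_months,
    TRUE ~ death_time
  )
  survival <- tibble(subject_id = ids, time_months = time, status = status)

  n_dl <- length(spec$dlt_prob_per_dose)
  tox <- tidyr::expand_grid(subject_id = ids,
                            cycle = seq_len(spec$max_cycles),
                            dose_level = seq_len(n_dl))
  u_dlt <- runif(nrow(tox))
  u_g2 <- runif(nrow(tox))
  tox$dlt <- u_dlt < spec$dlt_prob_per_dose[tox$dose_level]
  tox$grade2 <- !tox$dlt & u_g2 < spec$grade2_prob_per_dose[tox$dose_level]

  list(survival = survival, toxicity = tox)
}

#' Simulate synthetic infusion records
#'
#' Draws per-treatment infusion durations from a normal distribution
#' truncated at zero (defaults mean 361.6 min, sd 65 min, matching
#' observed CED infusion times) and attaches dose-level infusion volumes.
#'
#' @param n Number of infusions.
#' @param dose_levels Tibble from [dose_ladder()] giving `volume_mL`.
#' @param dose_level Integer vector (length 1 or `n`) of dose levels.
#' @param duration_mean_min,duration_sd_min Truncated-normal parameters.
#' @param seed Integer RNG seed.
#' @return Tibble with `ced_number`, `dose_level`, `vi_mL`,
#'   `duration_min`.
#' @export
generate_infusions <- function(n, dose_levels = dose_ladder(), dose_level = 1L,
                               duration_mean_min = 361.6, duration_sd_min = 65,
                               seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  dl <- rep_len(as.integer(dose_level), n)
  dur <- rnorm(n, duration_mean_min, duration_sd_min)
  while (any(dur <= 0)) dur[dur <= 0] <- rnorm(sum(dur <= 0), duration_mean_min, duration_sd_min)
  tibble(ced_number = seq_len(n), dose_level = dl,
         vi_mL = dose_levels$volume_mL[dl], duration_min = dur)
}
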