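#' Dose ladder
#'
#' Configured dose levels for the escalation design. Volumes must be
#' strictly increasing with the level index (the trial used 2 mL and
#' 3 mL of drug at 20 mg/mL for levels 1 and 2).
#'
#' @param volume_mL Infusion volume per dose level, strictly increasing.
#' @param concentration_mg_per_mL Drug concentration (scalar or per level).
#' @return Tibble with `dose_level`, `volume_mL`,
#'   `concentration_mg_per_mL`.
#' @export
dose_ladder <- function(volume_mL = c(2, 3), concentration_mg_per_mL = 20) {
  stopifnot(length(volume_mL) >= 1, all(volume_mL > 0))
  if (is.unsorted(volume_mL, strictly = TRUE)) {
    abort("dose_ladder: volumes must be strictly increasing with dose level")
  }
  tibble(dose_level = seq_along(volume_mL), volume_mL = volume_mL,
         concentration_mg_per_mL = rep_len(concentration_mg_per_mL, length(volume_mL)))
}

#' One treatment-cycle toxicity outcome
#'
#' The adjudicated toxicity summary of one patient-cycle, as fed to
#' [classify_dlt()] and [next_decision()]. `max_related_grade` is the
#' worst CTCAE grade judged related to the CED procedure or the infusate
#' (unrelated events do not enter the design rules);
#' `tolerable_grade2` records the clinical adjudication of a grade 2
#' event (tolerability cannot be computed); `n_related_grade2plus` is
#' the number of distinct related grade >= 2 adverse events in the cycle
#' (a single patient-cycle can contribute more than one occurrence to
#' the cohort tally).
#'
#' @param subject_id Identifier.
#' @param cycle Positive integer treatment cycle.
#' @param dose_level Dose level administered this cycle.
#' @param max_related_grade Worst related grade, 0-5.
#' @param tolerable_grade2 Was a related grade 2 event tolerable?
#' @param neurological Is the worst related event neurological?
#' @param related Relatedness flag for the worst event.
#' @param systemic_grade3plus Any systemic treatment-related grade >= 3
#'   toxicity?
#' @param managed_gi Was that systemic event nausea/vomiting/diarrhea
#'   controlled by maximal medical management (exempt from DLT)?
#' @param within_dlt_window Did the event fall within 14 days of the
#'   last infusion?
#' @param n_related_grade2plus Occurrence count for the cohort grade >= 2
#'   tally; defaults to 1 if `max_related_grade >= 2` else 0.
#' @return One-row tibble.
#' @export
cycle_outcome <- function(subject_id, cycle, dose_level, max_related_grade,
                          tolerable_grade2 = TRUE, neurological = TRUE,
                          related = TRUE, systemic_grade3plus = FALSE,
                          managed_gi = FALSE, within_dlt_window = TRUE,
                          n_related_grade2plus = NULL) {
  stopifnot(max_related_grade %in% 0:5, cycle >= 1, dose_level >= 1)
  n2 <- n_related_grade2plus %||% as.integer(max_related_grade >= 2)
  tibble(subject_id = as.character(subject_id), cycle = as.integer(cycle),
         dose_level = as.integer(dose_level),
         max_related_grade = as.integer(max_related_grade),
         tolerable_grade2 = tolerable_grade2, neurological = neurological,
         related = related, systemic_grade3plus = systemic_grade3plus,
         managed_gi = managed_gi, within_dlt_window = within_dlt_window,
         n_related_grade2plus = as.integer(n2))
}

#' Classify a cycle outcome as dose-limiting
#'
#' A dose-limiting toxicity is (1) any intolerable grade 2, or grade 3
#' or higher, neurological toxicity related to the CED procedure or
#' infusion, or (2) any systemic treatment-related grade 3 or higher
#' toxicity, excepting nausea/vomiting/diarrhea controlled by maximal
#' medical management — in either case occurring within the 14-day
#' window after the last infusion.
#'
#' @param outcome A [cycle_outcome()] row.
#' @return Logical.
#' @export
classify_dlt <- function(outcome) {
  stopifnot(nrow(outcome) == 1)
  neuro_dlt <- outcome$neurological && outcome$related &&
    (outcome$max_related_grade >= 3 ||
       (outcome$max_related_grade == 2 && !outcome$tolerable_grade2))
  systemic_dlt <- outcome$systemic_grade3plus && !outcome$managed_gi
  (neuro_dlt || systemic_dlt) && outcome$within_dlt_window
}

#' Initial state of the escalation design
#'
#' The design starts in accelerated-titration (ATD) phase: single-patient
#' cohorts escalate after grade 0-1 toxicity, stay after tolerable
#' grade 2, and the first cycle-1 DLT or the second cycle-1 related
#' grade >= 2 occurrence (cohort-wide) converts the design to a standard
#' 3+3 at the triggering dose level, the triggering patient counting
#' toward the first triplet.
#'
#' @param n_dose_levels Number of configured dose levels.
#' @param start_dl Starting dose level (default 1).
#' @param n_max Maximum number of patients enrollable.
#' @param keep_log Record an audit log of decisions (default `TRUE`;
#'   disable for the enumeration oracle).
#' @return A `design_state` list.
#' @export
design_init <- function(n_dose_levels, start_dl = 1L, n_max = 30L, keep_log = TRUE) {
  stopifnot(n_dose_levels >= 1, start_dl >= 1, start_dl <= n_dose_levels)
  structure(list(
    phase = "ATD", n_dose_levels = as.integer(n_dose_levels),
    current_dl = as.integer(start_dl), grade2plus_count_cycle1 = 0L,
    cohort_dl = NA_integer_, cohort_n = 0L, cohort_dlt = 0L, cohort_size = 3L,
    per_dl_enrolled = setNames(integer(n_dose_levels), seq_len(n_dose_levels)),
    per_dl_dlt = setNames(integer(n_dose_levels), seq_len(n_dose_levels)),
    n_enrolled = 0L, rp2d = NA_integer_, rp2d_declared = FALSE,
    n_max = as.integer(n_max), keep_log = keep_log,
    audit_log = if (keep_log) list() else NULL
  ), class = "design_state")
}

#' @export
print.design_state <- function(x, ...) {
  cat(sprintf("<design_state phase %s, current DL %d, enrolled %d%s>\n",
              x$phase, x$current_dl, x$n_enrolled,
              if (x$phase == "COMPLETE") {
                sprintf(", RP2D %s", ifelse(is.na(x$rp2d), "none", x$rp2d))
              } else ""))
  invisible(x)
}

log_decision <- function(state, outcome, action, rationale) {
  if (!state$keep_log) return(state)
  state$audit_log[[length(state$audit_log) + 1L]] <- tibble(
    step = length(state$audit_log) + 1L,
    subject_id = outcome$subject_id, cycle = outcome$cycle,
    dose_level = outcome$dose_level, dlt = classify_dlt(outcome),
    action = action, rationale = rationale, phase_after = state$phase,
    current_dl_after = state$current_dl
  )
  state
}

declare <- function(state, rp2d, action) {
  state$phase <- "COMPLETE"
  state$rp2d <- if (is.na(rp2d)) NA_integer_ else as.integer(rp2d)
  state$rp2d_declared <- TRUE
  list(action = action, state = state)
}

escalate_or_declare_3p3 <- function(state) {
  dl <- state$cohort_dl
  if (dl >= state$n_dose_levels) {
    return(declare(state, dl, "DECLARE_RP2D_CURRENT"))
  }
  state$current_dl <- dl + 1L
  state$cohort_dl <- dl + 1L
  state$cohort_n <- 0L
  state$cohort_dlt <- 0L
  state$cohort_size <- 3L
  list(action = "ESCALATE", state = state)
}

declare_next_lower <- function(state) {
  dl <- state$cohort_dl
  declare(state, if (dl > 1L) dl - 1L else NA_integer_, "DECLARE_RP2D_NEXT_LOWER")
}

#' Advance the escalation design by one cycle outcome
#'
#' The core decision rule of the design. In ATD phase (cycle-1
#' outcomes): related grade 0-1 escalates the next enrollment (at the
#' top level the current dose is declared the RP2D); tolerable grade 2
#' keeps the dose; a DLT de-escalates intra-patient; the first cycle-1
#' DLT or the second cycle-1 related grade >= 2 occurrence transitions
#' the design to 3+3 at the triggering level, queuing two additional
#' patients there. In 3+3 phase, each completed cohort is judged: 0/3
#' DLT escalates (or declares the top level the RP2D), 1/3 expands to
#' six, >= 2/3 declares the next lower level, 1/6 escalates, > 1/6
#' declares the next lower level. Later-cycle outcomes drive
#' intra-patient modification only (grade 0-1 may escalate, grade 2
#' stays, DLT de-escalates) without touching cohort bookkeeping.
#'
#' @param state A [design_init()] state (not yet COMPLETE).
#' @param outcome A [cycle_outcome()] row at the state's current dose
#'   level (cycle 1) or any configured level (later cycles).
#' @return List: `action` (decision string), `rationale`, `state`
#'   (updated).
#' @export
next_decision <- function(state, outcome) {
  stopifnot(inherits(state, "design_state"), nrow(outcome) == 1)
  if (state$phase == "COMPLETE") abort("next_decision: design already complete")
  dl <- outcome$dose_level
  if (dl < 1 || dl > state$n_dose_levels) {
    abort(sprintf("next_decision: outcome at unconfigured dose level %d", dl))
  }
  dlt <- classify_dlt(outcome)
  cycle1 <- outcome$cycle == 1L
  grade <- outcome$max_related_grade

  if (!cycle1) {
    # intra-patient dose modification only
    res <- if (dlt) {
      list(action = "DE_ESCALATE", state = state)
    } else if (grade >= 2) {
      list(action = "STAY", state = state)
    } else {
      list(action = "ESCALATE", state = state)
    }
    res$rationale <- "intra-patient modification (post cycle 1)"
    res$state <- log_decision(res$state, outcome, res$action, res$rationale)
    return(res)
  }

  state$n_enrolled <- state$n_enrolled + 1L
  state$per_dl_enrolled[dl] <- state$per_dl_enrolled[dl] + 1L
  if (dlt) state$per_dl_dlt[dl] <- state$per_dl_dlt[dl] + 1L

  if (state$phase == "ATD") {
    state$grade2plus_count_cycle1 <- state$grade2plus_count_cycle1 +
      outcome$n_related_grade2plus
    if (dlt || state$grade2plus_count_cycle1 >= 2L) {
      state$phase <- "THREE_PLUS_THREE"
      state$current_dl <- dl
      state$cohort_dl <- dl
      state$cohort_n <- 1L
      state$cohort_dlt <- if (dlt) 1L else 0L
      state$cohort_size <- 3L
      rationale <- if (dlt) "first cycle-1 DLT" else "second cycle-1 grade >= 2 occurrence"
      state <- log_decision(state, outcome, "TRANSITION_TO_3P3", rationale)
      return(list(action = "TRANSITION_TO_3P3", rationale = rationale, state = state))
    }
    if (dlt) {
      # unreachable in cycle 1 (a DLT transitions), kept for completeness
      state <- log_decision(state, outcome, "DE_ESCALATE", "DLT: intra-patient de-escalation")
      return(list(action = "DE_ESCALATE", rationale = "DLT", state = state))
    }
    if (grade >= 2) {
      state <- log_decision(state, outcome, "STAY", "tolerable grade 2: dose unchanged")
      return(list(action = "STAY", rationale = "tolerable grade 2", state = state))
    }
    if (state$current_dl < state$n_dose_levels) {
      state$current_dl <- state$current_dl + 1L
      state <- log_decision(state, outcome, "ESCALATE", "grade 0-1: escalation permitted")
      return(list(action = "ESCALATE", rationale = "grade 0-1", state = state))
    }
    res <- declare(state, state$current_dl, "DECLARE_RP2D_CURRENT")
    res$rationale <- "grade 0-1 at top dose level"
    res$state <- log_decision(res$state, outcome, res$action, res$rationale)
    return(res)
  }

  # THREE_PLUS_THREE, cycle-1 outcome
  if (dl == state$cohort_dl) {
    state$cohort_n <- state$cohort_n + 1L
    if (dlt) state$cohort_dlt <- state$cohort_dlt + 1L
  }
  if (state$cohort_n >= state$cohort_size) {
    d <- state$cohort_dlt
    if (state$cohort_size == 3L) {
      if (d == 0L) {
        res <- escalate_or_declare_3p3(state)
        res$rationale <- "0/3 DLT"
      } else if (d == 1L) {
        state$cohort_size <- 6L
        res <- list(action = "EXPAND_TO_6", state = state, rationale = "1/3 DLT")
      } else {
        res <- declare_next_lower(state)
        res$rationale <- ">= 2/3 DLT"
      }
    } else {
      if (d <= 1L) {
        res <- escalate_or_declare_3p3(state)
        res$rationale <- sprintf("%d/6 DLT", d)
      } else {
        res <- declare_next_lower(state)
        res$rationale <- "> 1/6 DLT"
      }
    }
  } else if (dlt) {
    res <- list(action = "DE_ESCALATE", state = state,
                rationale = "DLT: intra-patient de-escalation; cohort continues")
  } else {
    res <- list(action = "CONTINUE", state = state, rationale = "cohort incomplete")
  }
  res$state <- log_decision(res$state, outcome, res$action, res$rationale)
  res
}

#' Replay a recorded toxicity history through the design
#'
#' Feeds a sequence of [cycle_outcome()] rows to [next_decision()],
#' checking each against the design rules, and returns the decision
#' trace and final state.
#'
#' @param outcomes Tibble of [cycle_outcome()] rows, in enrollment
#'   order.
#' @param n_dose_levels,start_dl,n_max Passed to [design_init()].
#' @return List of class `design_replay`: `trace` tibble (one row per
#'   outcome: action, rationale, phase and current dose level after) and
#'   `state`.
#' @examples
#' replay_history(pnoc009_history(), n_dose_levels = 2)$trace
#' @export
replay_history <- function(outcomes, n_dose_levels, start_dl = 1L, n_max = 30L) {
  state <- design_init(n_dose_levels, start_dl = start_dl, n_max = n_max)
  rows <- vector("list", nrow(outcomes))
  for (i in seq_len(nrow(outcomes))) {
    out <- outcomes[i, ]
    res <- next_decision(state, out)
    state <- res$state
    rows[[i]] <- tibble(subject_id = out$subject_id, cycle = out$cycle,
                        dose_level = out$dose_level, dlt = classify_dlt(out),
                        action = res$action, rationale = res$rationale,
                        phase_after = state$phase,
                        current_dl_after = state$current_dl)
    if (state$phase == "COMPLETE") break
  }
  structure(list(trace = dplyr::bind_rows(rows), state = state),
            class = "design_replay")
}
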