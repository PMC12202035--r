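# Monte-Carlo harness and exact enumeration for the escalation design.
# A simulated patient's cycle-1 outcome is categorical per dose level:
# DLT with probability p_dlt[dl]; otherwise a tolerable related grade 2
# with probability p_grade2[dl]; otherwise grade 0-1.

sim_outcome <- function(kind, dl, subject_id, cycle = 1L) {
  switch(kind,
    dlt = cycle_outcome(subject_id, cycle, dl, max_related_grade = 3,
                        neurological = TRUE, related = TRUE),
    grade2 = cycle_outcome(subject_id, cycle, dl, max_related_grade = 2,
                           tolerable_grade2 = TRUE),
    ok = cycle_outcome(subject_id, cycle, dl, max_related_grade = 0)
  )
}

trial_outcome_label <- function(state) {
  if (state$phase != "COMPLETE") return("incomplete")
  if (is.na(state$rp2d)) return("none")
  paste0("rp2d_", state$rp2d)
}

#' Simulate one trial under the escalation design
#'
#' Draws cycle-1 outcomes patient by patient at the design's current
#' dose level and advances [next_decision()] until the design completes
#' or `n_max` patients have enrolled. Seeded and reproducible.
#'
#' @param p_dlt,p_grade2 Per-dose-level probabilities: `p_dlt[dl]` is
#'   the DLT probability, `p_grade2[dl]` the probability of a tolerable
#'   related grade 2 given no DLT.
#' @param n_max Maximum enrollment.
#' @param seed Integer RNG seed.
#' @param start_dl Starting dose level.
#' @param keep_log Record the decision trace (disable for speed in bulk
#'   simulation).
#' @return List of class `trial_result`: `rp2d` (dose level or `NA`),
#'   `outcome` (`"rp2d_<k>"`, `"none"`, `"incomplete"`), `n_enrolled`,
#'   `completed`, `trace` (decision tibble), `state`.
#' @examples
#' simulate_trial(p_dlt = c(0.05, 0.6), p_grade2 = c(0.1, 0.2), seed = 7)
#' @export
simulate_trial <- function(p_dlt, p_grade2, n_max = 30L, seed = 1L, start_dl = 1L,
                           keep_log = TRUE) {
  stopifnot(length(p_dlt) == length(p_grade2),
            all(p_dlt >= 0 & p_dlt <= 1), all(p_grade2 >= 0 & p_grade2 <= 1),
            n_max >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  state <- design_init(length(p_dlt), start_dl = start_dl, n_max = n_max,
                       keep_log = keep_log)
  while (state$phase != "COMPLETE" && state$n_enrolled < n_max) {
    dl <- state$current_dl
    u <- runif(1)
    kind <- if (u < p_dlt[dl]) "dlt"
            else if (u < p_dlt[dl] + (1 - p_dlt[dl]) * p_grade2[dl]) "grade2"
            else "ok"
    out <- sim_outcome(kind, dl, sprintf("SIM-%03d", state$n_enrolled + 1L))
    state <- next_decision(state, out)$state
  }
  structure(list(
    rp2d = state$rp2d, outcome = trial_outcome_label(state),
    n_enrolled = state$n_enrolled, completed = state$phase == "COMPLETE",
    trace = dplyr::bind_rows(state$audit_log), state = state
  ), class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result: %s after %d patients>\n", x$outcome, x$n_enrolled))
  invisible(x)
}

#' @rdname simulate_trial
#' @param x A `trial_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.trial_result <- function(x, ...) x$trace

#' @rdname simulate_trial
#' @exportS3Method generics::glance
glance.trial_result <- function(x, ...) {
  tibble(outcome = x$outcome, rp2d = x$rp2d, n_enrolled = x$n_enrolled,
         completed = x$completed)
}

#' Operating characteristics by repeated simulation
#'
#' @param reps Number of simulated trials.
#' @inheritParams simulate_trial
#' @return Tibble with `outcome`, `n_trials`, `proportion`, and mean
#'   enrollment per outcome.
#' @export
trial_operating_characteristics <- function(p_dlt, p_grade2, reps = 1000L,
                                            n_max = 30L, seed = 1L, start_dl = 1L) {
  runs <- purrr::map(seq_len(reps), function(i) {
    r <- simulate_trial(p_dlt, p_grade2, n_max = n_max,
                        seed = derive_seed(seed, paste0("trial", i)),
                        start_dl = start_dl, keep_log = FALSE)
    tibble(outcome = r$outcome, n_enrolled = r$n_enrolled)
  })
  dplyr::bind_rows(runs) %>%
    dplyr::group_by(.data$outcome) %>%
    dplyr::summarise(n_trials = dplyr::n(),
                     mean_enrolled = mean(.data$n_enrolled), .groups = "drop") %>%
    dplyr::mutate(proportion = .data$n_trials / reps)
}

#' Exact trial-outcome distribution by decision-tree enumeration
#'
#' Recursively enumerates every per-patient outcome branch (DLT /
#' tolerable grade 2 / grade 0-1) through the same [next_decision()]
#' state machine, accumulating exact path probabilities, with
#' memoisation on the decision-relevant state. This is the closed-form
#' counterpart of [simulate_trial()] used to validate the Monte-Carlo
#' operating characteristics.
#'
#' @inheritParams simulate_trial
#' @return Tibble with `outcome` and exact `probability` (sums to 1).
#' @export
enumerate_trial <- function(p_dlt, p_grade2, n_max = 30L, start_dl = 1L) {
  stopifnot(length(p_dlt) == length(p_grade2))
  cache <- new.env(parent = emptyenv())
  add_into <- function(a, b) {
    for (nm in names(b)) a[nm] <- (if (nm %in% names(a)) a[[nm]] else 0) + b[[nm]]
    a
  }
  state_key <- function(s) {
    paste(s$phase, s$current_dl, min(s$grade2plus_count_cycle1, 2L),
          s$cohort_dl, s$cohort_n, s$cohort_dlt, s$cohort_size,
          s$n_enrolled, sep = "|")
  }
  recurse <- function(state) {
    if (state$phase == "COMPLETE" || state$n_enrolled >= n_max) {
      out <- trial_outcome_label(state)
      return(setNames(1, out))
    }
    key <- state_key(state)
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    dl <- state$current_dl
    pd <- p_dlt[dl]
    pg <- (1 - pd) * p_grade2[dl]
    po <- 1 - pd - pg
    probs <- c(dlt = pd, grade2 = pg, ok = po)
    acc <- numeric(0)
    for (kind in names(probs)) {
      if (probs[[kind]] <= 0) next
      out <- sim_outcome(kind, dl, "ENUM")
      child <- next_decision(state, out)$state
      acc <- add_into(acc, probs[[kind]] * recurse(child))
    }
    assign(key, acc, envir = cache)
    acc
  }
  state <- design_init(length(p_dlt), start_dl = start_dl, n_max = n_max,
                       keep_log = FALSE)
  dist <- recurse(state)
  tibble(outcome = names(dist), probability = as.numeric(dist)) %>%
    dplyr::arrange(.data$outcome)
}
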