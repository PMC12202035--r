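test_that("DLT classification follows the protocol definition", {
  # related grade 3 neurological toxicity within the window
  expect_true(classify_dlt(cycle_outcome("A", 1, 2, max_related_grade = 3)))
  # same event outside the 14-day window does not count
  expect_false(classify_dlt(cycle_outcome("A", 1, 2, max_related_grade = 3,
                                          within_dlt_window = FALSE)))
  # unrelated grade 3 (e.g. dysarthria adjudicated unrelated) is not a DLT
  expect_false(classify_dlt(cycle_outcome("A", 1, 2, max_related_grade = 3,
                                          related = FALSE)))
  # intolerable related grade 2 neurological toxicity is a DLT
  expect_true(classify_dlt(cycle_outcome("A", 1, 2, max_related_grade = 2,
                                         tolerable_grade2 = FALSE)))
  # tolerable grade 2 is not
  expect_false(classify_dlt(cycle_outcome("A", 1, 2, max_related_grade = 2)))
  # systemic grade >= 3 is a DLT unless managed nausea/vomiting/diarrhea
  expect_true(classify_dlt(cycle_outcome("A", 1, 2, max_related_grade = 0,
                                         systemic_grade3plus = TRUE)))
  expect_false(classify_dlt(cycle_outcome("A", 1, 2, max_related_grade = 0,
                                          systemic_grade3plus = TRUE,
                                          managed_gi = TRUE)))
  # grade 0 is never dose-limiting
  expect_false(classify_dlt(cycle_outcome("A", 1, 1, max_related_grade = 0)))
})

test_that("the six-patient trial history replays without rule violation", {
  rep <- replay_history(pnoc009_history(), n_dose_levels = 2)
  tr <- rep$trace

  # patient 1: clean cycle at DL1 escalates enrollment to DL2
  expect_equal(tr$action[1], "ESCALATE")
  expect_equal(tr$current_dl_after[1], 2L)
  # patient 2: second related grade 2 in cycle 1 converts the design
  expect_equal(tr$action[2], "TRANSITION_TO_3P3")
  expect_match(tr$rationale[2], "second cycle-1 grade")
  expect_equal(tr$phase_after[2], "THREE_PLUS_THREE")
  expect_equal(tr$current_dl_after[2], 2L)
  # patient 3: the DLT prompts intra-patient de-escalation, cohort stays at DL2
  expect_true(tr$dlt[3])
  expect_equal(tr$action[3], "DE_ESCALATE")
  expect_equal(tr$current_dl_after[3], 2L)
  # patient 4 completes the triplet with 1/3 DLTs: expansion to six
  expect_equal(tr$action[4], "EXPAND_TO_6")
  # patients 5 and 6 continue the expansion cohort
  expect_equal(tr$action[5:6], c("CONTINUE", "CONTINUE"))

  # the trial stopped before the expansion completed: no RP2D
  expect_false(rep$state$phase == "COMPLETE")
  expect_true(is.na(rep$state$rp2d))
  expect_equal(rep$state$n_enrolled, 6L)
  expect_equal(unname(rep$state$per_dl_enrolled), c(1L, 5L))
})

test_that("intra-patient modification after cycle 1 leaves cohort bookkeeping alone", {
  state <- design_init(2)
  r1 <- next_decision(state, cycle_outcome("P1", 1, 1, max_related_grade = 0))
  n_before <- r1$state$n_enrolled
  # a later-cycle DLT de-escalates the patient but enrolls nobody
  r2 <- next_decision(r1$state, cycle_outcome("P1", 2, 2, max_related_grade = 3))
  expect_equal(r2$action, "DE_ESCALATE")
  expect_equal(r2$state$n_enrolled, n_before)
  # later-cycle tolerable grade 2 stays, grade 1 escalates (intra-patient)
  expect_equal(next_decision(r1$state, cycle_outcome("P1", 2, 2, max_related_grade = 2))$action, "STAY")
  expect_equal(next_decision(r1$state, cycle_outcome("P1", 2, 2, max_related_grade = 1))$action, "ESCALATE")
})

test_that("every reachable outcome maps to exactly one legal action in either phase", {
  actions <- c("ESCALATE", "STAY", "DE_ESCALATE", "TRANSITION_TO_3P3",
               "EXPAND_TO_6", "DECLARE_RP2D_NEXT_LOWER",
               "DECLARE_RP2D_CURRENT", "CONTINUE")
  grid <- tidyr::expand_grid(grade = 0:5, tolerable = c(TRUE, FALSE),
                             cycle = c(1L, 2L))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    out <- cycle_outcome("X", g$cycle, 1, max_related_grade = g$grade,
                         tolerable_grade2 = g$tolerable)
    # ATD phase
    res <- next_decision(design_init(2), out)
    expect_true(res$action %in% actions)
    # 3+3 phase (reach it via a transition first)
    st <- next_decision(design_init(2),
                        cycle_outcome("T", 1, 1, max_related_grade = 3))$state
    expect_equal(st$phase, "THREE_PLUS_THREE")
    res3 <- next_decision(st, out)
    expect_true(res3$action %in% actions)
    # dose never leaves the configured ladder
    expect_gte(res3$state$current_dl, 1L)
    expect_lte(res3$state$current_dl, 2L)
  }
  expect_error(next_decision(design_init(2), cycle_outcome("X", 1, 3, 0)),
               "unconfigured dose level")
})

test_that("degenerate toxicity profiles force the textbook trial outcomes", {
  # no toxicity anywhere: monotone escalation, RP2D at the top level
  clean <- simulate_trial(p_dlt = c(0, 0, 0), p_grade2 = c(0, 0, 0), seed = 1)
  expect_equal(clean$outcome, "rp2d_3")
  expect_equal(clean$n_enrolled, 3L)
  expect_true(all(tidy(clean)$action %in% c("ESCALATE", "DECLARE_RP2D_CURRENT")))

  # certain DLT: immediate transition and >= 2/3 DLTs at the floor, no RP2D
  toxic <- simulate_trial(p_dlt = c(1, 1), p_grade2 = c(0, 0), seed = 1)
  expect_equal(toxic$outcome, "none")
  expect_equal(tidy(toxic)$action[1], "TRANSITION_TO_3P3")
})

test_that("simulation is reproducible and its trace replays deterministically", {
  a <- simulate_trial(p_dlt = c(0.2, 0.5), p_grade2 = c(0, 0), seed = 99)
  b <- simulate_trial(p_dlt = c(0.2, 0.5), p_grade2 = c(0, 0), seed = 99)
  expect_identical(tidy(a), tidy(b))
  expect_identical(glance(a), glance(b))

  # replaying the recorded outcomes through the state machine reproduces
  # the decision sequence
  trace <- tidy(a)
  kinds <- ifelse(trace$dlt, "dlt", "ok")
  outs <- dplyr::bind_rows(purrr::map2(kinds, trace$dose_level, function(k, dl) {
    cycle_outcome("R", 1, dl,
                  max_related_grade = if (k == "dlt") 3 else 0)
  }))
  rep <- replay_history(outs, n_dose_levels = 2)
  expect_equal(rep$trace$action, trace$action)
})

test_that("Monte-Carlo RP2D frequencies agree with exhaustive enumeration", {
  p_dlt <- c(0.05, 0.60)
  p_g2 <- c(0.10, 0.20)
  exact <- enumerate_trial(p_dlt, p_g2, n_max = 30)
  expect_equal(sum(exact$probability), 1, tolerance = 1e-9)

  reps <- 2000L
  oc <- trial_operating_characteristics(p_dlt, p_g2, reps = reps, seed = 12)
  merged <- dplyr::left_join(exact, oc, by = "outcome") %>%
    dplyr::mutate(proportion = dplyr::coalesce(proportion, 0))
  for (i in seq_len(nrow(merged))) {
    p <- merged$probability[i]
    se <- sqrt(p * (1 - p) / reps)
    expect_lt(abs(merged$proportion[i] - p), max(3 * se, 3 / reps))
  }
})
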