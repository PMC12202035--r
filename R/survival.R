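#' Convert survival records to (time, event) pairs under a
#' lost-to-follow-up policy
#'
#' Overall survival runs from diagnosis to death; patients without a
#' recorded death contribute their off-study time. A patient lost to
#' follow-up can be handled two ways, and a small cohort makes the
#' choice material: `"lost_as_event"` treats the loss as an event at the
#' recorded time (conservative), `"lost_censored"` censors it (the usual
#' convention).
#'
#' @param records Tibble with `time_months` (> 0) and `status`
#'   (`"death"`, `"alive"`, `"lost"`); extra columns are carried along.
#' @param policy `"lost_as_event"` or `"lost_censored"`.
#' @return Tibble with `time` and `event` (1 = event, 0 = censored).
#' @examples
#' apply_lost_policy(pnoc009_patients() |>
#'   dplyr::rename(time_months = followup_months), "lost_as_event")
#' @export
apply_lost_policy <- function(records, policy = c("lost_as_event", "lost_censored")) {
  policy <- match.arg(policy)
  if (nrow(records) == 0) return(tibble(time = numeric(), event = integer()))
  status <- tolower(records$status)
  ok <- status %in% c("death", "alive", "lost")
  if (!all(ok)) {
    abort(paste("apply_lost_policy: unknown status value(s):",
                paste(unique(records$status[!ok]), collapse = ", ")))
  }
  if (any(records$time_months <= 0)) abort("apply_lost_policy: time_months must be positive")
  event <- dplyr::case_when(
    status == "death" ~ 1L,
    status == "alive" ~ 0L,
    policy == "lost_as_event" ~ 1L,
    TRUE ~ 0L
  )
  tibble(time = records$time_months, event = event)
}

#' Kaplan-Meier fit with log-transformed Greenwood confidence intervals
#'
#' Product-limit estimator of the survival function with pointwise 95%
#' confidence intervals of the form `exp(log S +/- 1.96 * se(log S))`
#' (Greenwood variance on the log scale), truncated to `[0, 1]`. Deaths
#' precede censorings at tied times (the standard convention). The fit
#' is delegated to [survival::survfit()].
#'
#' @param data Tibble with `time` and `event` columns (see
#'   [apply_lost_policy()]).
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `km_curve` wrapping a per-time tibble
#'   (`time`, `n_risk`, `n_event`, `n_censor`, `estimate`, `ci_lower`,
#'   `ci_upper`) plus `n` and `n_events`.
#' @examples
#' d <- apply_lost_policy(pnoc009_patients() |>
#'   dplyr::rename(time_months = followup_months), "lost_censored")
#' km <- km_fit(d)
#' os_at(km, 12)
#' @export
km_fit <- function(data, conf_level = 0.95) {
  stopifnot(nrow(data) >= 1, all(c("time", "event") %in% names(data)))
  fit <- survival::survfit(survival::Surv(data$time, data$event) ~ 1,
                           conf.type = "log", conf.int = conf_level)
  s <- summary(fit, censored = TRUE)
  curve <- tibble(
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, estimate = s$surv,
    ci_lower = pmin(pmax(ifelse(is.na(s$lower), 0, s$lower), 0), 1),
    ci_upper = pmin(ifelse(is.na(s$upper), 1, s$upper), 1)
  )
  # degenerate cases: before the first event (se = 0) and after the curve
  # hits zero (log CI undefined) the interval collapses to the estimate
  degen <- cumsum(curve$n_event) == 0 | curve$estimate == 0
  curve$ci_lower[degen] <- curve$estimate[degen]
  curve$ci_upper[degen] <- curve$estimate[degen]
  structure(list(curve = curve, n = nrow(data), n_events = sum(data$event),
                 conf_level = conf_level),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve: n = %d, events = %d, median = %s months>\n",
              x$n, x$n_events,
              ifelse(is.na(median_survival(x)), "not reached",
                     format(median_survival(x)))))
  print(x$curve)
  invisible(x)
}

#' Survival probability (and CI) at a time point
#'
#' Right-continuous step-function lookup: the estimate at the last event
#' time at or before `t` (1 before the first event). Querying beyond the
#' last follow-up returns the last defined value with `truncated = TRUE`.
#'
#' @param curve A [km_fit()] result.
#' @param t Nonnegative time (months).
#' @return One-row tibble: `time`, `estimate`, `ci_lower`, `ci_upper`,
#'   `truncated`.
#' @export
os_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), t >= 0)
  cv <- curve$curve
  truncated <- t > max(cv$time)
  at <- which(cv$time <= t)
  if (length(at) == 0) {
    return(tibble(time = t, estimate = 1, ci_lower = 1, ci_upper = 1,
                  truncated = FALSE))
  }
  i <- max(at)
  tibble(time = t, estimate = cv$estimate[i], ci_lower = cv$ci_lower[i],
         ci_upper = cv$ci_upper[i], truncated = truncated)
}

#' Median survival time
#'
#' Smallest event time at which the survival curve reaches 0.5 or below;
#' `NA` if the curve never does.
#'
#' @param curve A [km_fit()] result.
#' @return Median time in months, or `NA_real_`.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  cv <- curve$curve[curve$curve$n_event > 0, ]
  below <- cv$time[cv$estimate <= 0.5 + 1e-12]
  if (length(below) == 0) NA_real_ else min(below)
}

#' @rdname km_fit
#' @param x A `km_curve`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.km_curve <- function(x, ...) x$curve

#' @rdname km_fit
#' @exportS3Method generics::glance
glance.km_curve <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, median = median_survival(x),
         conf_level = x$conf_level)
}

#' @rdname km_fit
#' @param object A `km_curve`.
#' @exportS3Method ggplot2::autoplot
autoplot.km_curve <- function(object, ...) {
  cv <- dplyr::bind_rows(
    tibble(time = 0, estimate = 1, ci_lower = 1, ci_upper = 1),
    object$curve[, c("time", "estimate", "ci_lower", "ci_upper")]
  )
  n <- nrow(cv)
  steps <- tibble(
    time = rep(cv$time, each = 2)[-1],
    estimate = rep(cv$estimate, each = 2)[-(2 * n)],
    ci_lower = rep(cv$ci_lower, each = 2)[-(2 * n)],
    ci_upper = rep(cv$ci_upper, each = 2)[-(2 * n)]
  )
  censored <- object$curve[object$curve$n_censor > 0, ]
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = censored, shape = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Months from diagnosis", y = "Overall survival",
                  title = "Kaplan-Meier overall survival") +
    ggplot2::theme_minimal()
}

#' Survival endpoints under both lost-to-follow-up policies
#'
#' Convenience wrapper fitting the Kaplan-Meier curve under each policy
#' and extracting the survival probability at `at_months` and the median.
#'
#' @param records See [apply_lost_policy()].
#' @param at_months Landmark time (default 12 months).
#' @return Tibble with one row per policy: `policy`, `os_estimate`,
#'   `os_ci_lower`, `os_ci_upper` (all on the probability scale),
#'   `median_months`, `n`, `n_events`.
#' @export
survival_endpoints <- function(records, at_months = 12) {
  purrr::map_dfr(c("lost_as_event", "lost_censored"), function(pol) {
    km <- km_fit(apply_lost_policy(records, pol))
    at <- os_at(km, at_months)
    tibble(policy = pol, os_estimate = at$estimate,
           os_ci_lower = at$ci_lower, os_ci_upper = at$ci_upper,
           median_months = median_survival(km), n = km$n,
           n_events = km$n_events)
  })
}
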