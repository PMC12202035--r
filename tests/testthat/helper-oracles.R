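# Independent oracles used to validate the implementation paths.

# Hand-rolled product-limit estimator with log-transformed Greenwood CI.
# Deaths precede censorings at tied times. Returns one row per distinct
# time in the data.
km_oracle <- function(time, event, conf_level = 0.95) {
  ord <- order(time, -event)
  time <- time[ord]; event <- event[ord]
  times <- sort(unique(time))
  n <- length(time)
  s <- 1
  var_log <- 0
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(time = times, n_risk = NA_real_, n_event = NA_real_,
                    estimate = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_)
  for (i in seq_along(times)) {
    t <- times[i]
    at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    if (d > 0) {
      s <- s * (1 - d / at_risk)
      if (at_risk > d) var_log <- var_log + d / (at_risk * (at_risk - d))
    }
    out$n_risk[i] <- at_risk
    out$n_event[i] <- d
    out$estimate[i] <- s
    if (s > 0 && var_log > 0) {
      se <- sqrt(var_log)
      out$ci_lower[i] <- max(0, exp(log(s) - z * se))
      out$ci_upper[i] <- min(1, exp(log(s) + z * se))
    } else {
      out$ci_lower[i] <- s
      out$ci_upper[i] <- s
    }
  }
  out
}

# two-pass mean / sample-variance oracle
mean_sd_oracle <- function(x) {
  m <- sum(x) / length(x)
  v <- sum((x - m)^2) / (length(x) - 1)
  c(mean = m, sd = sqrt(v))
}

# the six published survival records, built in code
pnoc_survival_records <- function() {
  dplyr::rename(pnoc009_patients(), time_months = followup_months)
}

expect_masks_equal <- function(a, b) {
  expect_identical(dim(a$voxels), dim(b$voxels))
  expect_identical(which(a$voxels), which(b$voxels))
}
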