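#' Round half away from zero
#'
#' Presentation rounding used for all printed volumes and percentages:
#' ties go away from zero (so 16.65 -> 16.7), unlike base [round()]'s
#' round-half-even. Internal computation always keeps full precision;
#' this is applied only when formatting results.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(c(0.5, 1.25, -0.5), 0:1 * 0 + 0)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by a few ulps so decimal values that land a hair below .5 in
  # binary (e.g. mean(c(16.6, ...)) = 35.35 - eps) still round as printed
  z <- abs(x) * p
  sign(x) * floor(z + 0.5 + sqrt(.Machine$double.eps) * z) / p
}

# sample (n-1) and population (n) standard deviations; summary tables
# report both because published tables mix the two conventions
sd_sample <- function(x) stats::sd(x)
sd_population <- function(x) {
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}

# deterministic child seed derived from a user seed and a stage label;
# multiplicative string hash so nearby labels map to well-separated
# seeds, kept inside 32-bit integer range
derive_seed <- function(seed, label) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(label)) h <- (h * 69069 + ch) %% 2147483647
  as.integer(h)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
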