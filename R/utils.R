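# Internal helpers shared across modules.

# Canonical factor levels; reference coding uses the first level,
# which is the alphabetically first everywhere (fixed for reproducibility).
.arm_levels      <- c("mobile_web", "telephone")
.sex_levels      <- c("female", "male")
.age_levels      <- c("19-39", "40-59", "60-69", "70+")
.care_levels     <- c("medical", "surgical_other")
.hospital_levels <- c("A", "B", "C", "D")

.strata_vars <- c("sex", "age_group", "care_field", "hospital")

.strata_levels <- function() {
  list(sex = .sex_levels, age_group = .age_levels,
       care_field = .care_levels, hospital = .hospital_levels)
}

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (the convention used when formatting printed tables), unlike base
#' [round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic child seed for stage-level RNG streams, kept below 2^31.
.child_seed <- function(seed, stage) {
  (as.numeric(seed) %% 1000003) * 2099 + stage * 101 + 17
}

.is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)
}

# Moments of a normal censored to [lo, hi] (point masses at the bounds).
.censored_mean <- function(mu, sigma, lo = 0, hi = 100) {
  al <- (lo - mu) / sigma
  be <- (hi - mu) / sigma
  Fa <- stats::pnorm(al); Fb <- stats::pnorm(be)
  fa <- stats::dnorm(al); fb <- stats::dnorm(be)
  lo * Fa + hi * (1 - Fb) + mu * (Fb - Fa) + sigma * (fa - fb)
}

.censored_var <- function(mu, sigma, lo = 0, hi = 100) {
  al <- (lo - mu) / sigma
  be <- (hi - mu) / sigma
  Fa <- stats::pnorm(al); Fb <- stats::pnorm(be)
  fa <- stats::dnorm(al); fb <- stats::dnorm(be)
  m1 <- lo * Fa + hi * (1 - Fb) + mu * (Fb - Fa) + sigma * (fa - fb)
  mid2 <- mu^2 * (Fb - Fa) + 2 * mu * sigma * (fa - fb) +
    sigma^2 * ((Fb - Fa) - be * fb + al * fa)
  m2 <- lo^2 * Fa + hi^2 * (1 - Fb) + mid2
  pmax(m2 - m1^2, 0)
}
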