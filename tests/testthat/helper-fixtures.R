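# Shared fixtures, built in code.

# Small hand-specified generator config for fast tests.
simple_config <- function(n_per_arm = 300,
                          arm_effect = -4,
                          mnar_shift = c(telephone = 0, mobile_web = 0),
                          response_intercept = -0.5,
                          response_arm = 0.5,
                          intercept = 70,
                          sd = 12,
                          seed = 1L) {
  trial_config(
    n_per_arm = n_per_arm,
    strata_probs = list(
      sex = c(female = 0.5, male = 0.5),
      age_group = c("19-39" = 0.2, "40-59" = 0.3, "60-69" = 0.3, "70+" = 0.2),
      care_field = c(medical = 0.4, surgical_other = 0.6),
      hospital = c(A = 0.3, B = 0.3, C = 0.2, D = 0.2)
    ),
    response = list(intercept = response_intercept, arm = response_arm,
                    sex = c(male = 0.3),
                    age_group = c("40-59" = 0.2, "60-69" = 0.1, "70+" = -0.4),
                    care_field = c(surgical_other = 0.1),
                    hospital = c(B = -0.1, C = -0.5, D = -0.3)),
    outcome = list(intercept = intercept, arm_effect = arm_effect,
                   sex = c(male = 1),
                   age_group = c("40-59" = 1, "60-69" = 2, "70+" = 3),
                   care_field = c(surgical_other = 1),
                   hospital = c(B = -1, C = -2, D = -1),
                   sd = sd),
    mnar_shift = mnar_shift,
    seed = seed
  )
}

# Minimal patient data.frame (no generator) with chosen arms/strata,
# response indicators and, optionally, raw items all at a fixed level.
make_patients <- function(arm, responded,
                          sex = "female", age_group = "19-39",
                          care_field = "medical", hospital = "A") {
  n <- length(arm)
  df <- data.frame(
    patient_id = sprintf("X%04d", seq_len(n)),
    arm = factor(arm, levels = c("mobile_web", "telephone")),
    sex = factor(rep_len(sex, n), levels = c("female", "male")),
    age_group = factor(rep_len(age_group, n),
                       levels = c("19-39", "40-59", "60-69", "70+")),
    care_field = factor(rep_len(care_field, n),
                        levels = c("medical", "surgical_other")),
    hospital = factor(rep_len(hospital, n), levels = c("A", "B", "C", "D")),
    responded = responded,
    stringsAsFactors = FALSE
  )
  for (q in paste0("q", 1:21)) df[[q]] <- NA
  df$q13 <- NA_character_
  df
}

# 24-record IPW fixture: two hospitals with response probabilities
# 0.5 (A) and 0.25 (B), identical in both arms, chosen so the
# main-effects logistic MLE reproduces the cell rates exactly.
# Outcomes are fixed numbers for hand computation.
ipw_fixture <- function(mult = 1) {
  rows <- rbind(
    # arm, hospital, n, n_resp
    data.frame(arm = "telephone", hospital = "A", n = 4, n_resp = 2),
    data.frame(arm = "telephone", hospital = "B", n = 8, n_resp = 2),
    data.frame(arm = "mobile_web", hospital = "A", n = 4, n_resp = 2),
    data.frame(arm = "mobile_web", hospital = "B", n = 8, n_resp = 2)
  )
  rows$n <- rows$n * mult
  rows$n_resp <- rows$n_resp * mult
  arm <- rep(rows$arm, rows$n)
  hospital <- rep(rows$hospital, rows$n)
  responded <- unlist(mapply(function(n, r) c(rep(TRUE, r), rep(FALSE, n - r)),
                             rows$n, rows$n_resp, SIMPLIFY = FALSE))
  df <- make_patients(arm, responded, hospital = hospital)
  # respondent outcomes (telephone A, telephone B, mobile A, mobile B)
  y <- rep(NA_real_, nrow(df))
  y[df$responded & df$arm == "telephone" & df$hospital == "A"] <- c(80, 90)
  y[df$responded & df$arm == "telephone" & df$hospital == "B"] <- c(70, 75)
  y[df$responded & df$arm == "mobile_web" & df$hospital == "A"] <- c(60, 90)
  y[df$responded & df$arm == "mobile_web" & df$hospital == "B"] <- c(65, 95)
  list(data = df, y = y)
}

# Hand-computed Hajek contrast for the fixture: weights 2 (hospital A)
# and 4 (hospital B).
ipw_fixture_truth <- function() {
  # telephone: (2*80 + 2*90 + 4*70 + 4*75) / (2+2+4+4)
  mu_t <- (2 * 80 + 2 * 90 + 4 * 70 + 4 * 75) / 12
  mu_m <- (2 * 60 + 2 * 90 + 4 * 65 + 4 * 95) / 12
  mu_m - mu_t
}

# Delete-one jackknife of the IPW contrast (refitting the propensity
# model on every leave-one-out set): an independent variance oracle.
ipw_jackknife_se <- function(df, y) {
  n <- nrow(df)
  theta <- vapply(seq_len(n), function(i) {
    d <- df[-i, , drop = FALSE]
    fit <- fit_response_propensity(d)
    ipw_difference(d, y[-i], fit)$diff
  }, numeric(1))
  sqrt((n - 1) / n * sum((theta - mean(theta))^2))
}
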