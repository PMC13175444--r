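test_that("unadjusted difference matches hand computation on a tiny fixture", {
  df <- make_patients(arm = c(rep("telephone", 2), rep("mobile_web", 4)),
                      responded = TRUE)
  y <- c(80, 90, 60, 70, 80, 90)
  res <- unadjusted_difference(df, y)
  expect_equal(res$diff, 75 - 85)
  expect_equal(res$n_analyzed, 6)
  expect_true(res$ci95[1] <= res$diff && res$diff <= res$ci95[2])
})

test_that("identical outcome distributions give zero difference and p = 1", {
  df <- make_patients(arm = rep(c("telephone", "mobile_web"), each = 4),
                      responded = TRUE)
  y <- rep(c(60, 70, 80, 90), 2)
  res <- unadjusted_difference(df, y)
  expect_equal(res$diff, 0)
  expect_equal(res$p_value, 1)
})

test_that("arms with fewer than two respondents are rejected", {
  df <- make_patients(arm = c("telephone", rep("mobile_web", 3)),
                      responded = c(TRUE, TRUE, TRUE, FALSE))
  expect_error(unadjusted_difference(df, c(80, 70, 75, NA)), "2 respondents")
})

test_that("propensity fit reproduces exact half-response and unit weights", {
  # every covariate pattern has exactly half respondents: MLE gives 0.5
  base <- expand.grid(arm = c("telephone", "mobile_web"),
                      hospital = c("A", "B"), sex = c("female", "male"),
                      stringsAsFactors = FALSE)
  df <- make_patients(arm = rep(base$arm, each = 2),
                      responded = rep(c(TRUE, FALSE), nrow(base)),
                      hospital = rep(base$hospital, each = 2),
                      sex = rep(base$sex, each = 2))
  fit <- fit_response_propensity(df)
  expect_equal(unname(fit$pi), rep(0.5, nrow(df)), tolerance = 1e-8)
  expect_equal(unname(fit$weights[df$responded]), rep(2, sum(df$responded)),
               tolerance = 1e-8)
})

test_that("propensity coefficients are recovered on synthetic data", {
  cfg <- simple_config(n_per_arm = 4000)
  trial <- generate_trial(cfg, seed = 14)
  fit <- fit_response_propensity(trial)
  sm <- summary(fit$model)$coefficients
  truth <- c("(Intercept)" = cfg$response$intercept,
             "armtelephone" = -cfg$response$arm,
             "sexmale" = unname(cfg$response$sex["male"]),
             "care_fieldsurgical_other" = unname(cfg$response$care_field["surgical_other"]),
             "hospitalC" = unname(cfg$response$hospital["C"]))
  # intercept of the fit is at the reference arm (mobile_web)
  truth["(Intercept)"] <- cfg$response$intercept + cfg$response$arm
  for (nm in names(truth)) {
    expect_lt(abs(sm[nm, "Estimate"] - truth[nm]), 3 * sm[nm, "Std. Error"])
  }
})

test_that("separation is detected and reported", {
  df <- make_patients(arm = rep(c("telephone", "mobile_web"), each = 8),
                      responded = rep(c(TRUE, FALSE), 8),
                      hospital = rep(c("A", "B"), each = 8))
  df$responded[df$hospital == "B"] <- FALSE  # a stratum with zero respondents
  expect_error(fit_response_propensity(df), "separation")
  df_all <- make_patients(arm = "telephone", responded = rep(TRUE, 4))
  expect_error(fit_response_propensity(df_all), "both response outcomes")
})

test_that("IPW equals unadjusted under full response and constant weights", {
  df <- make_patients(arm = rep(c("telephone", "mobile_web"), each = 5),
                      responded = TRUE)
  set.seed(21)
  y <- round(stats::runif(10, 50, 100))
  un <- unadjusted_difference(df, y)
  ip1 <- ipw_difference(df, y, fit = propensity_fit(rep(1, 10), data = df))
  expect_equal(ip1$diff, un$diff)
  # constant weights within arm: Hajek invariance
  pi_const <- ifelse(df$arm == "telephone", 0.8, 0.4)
  ip2 <- ipw_difference(df, y, fit = propensity_fit(pi_const, data = df))
  expect_equal(ip2$diff, un$diff)
})

test_that("Hajek estimate is invariant to rescaling all weights", {
  fx <- ipw_fixture()
  pi <- ifelse(fx$data$hospital == "A", 0.5, 0.25)
  a <- ipw_difference(fx$data, fx$y, propensity_fit(pi, data = fx$data))
  b <- ipw_difference(fx$data, fx$y, propensity_fit(pi * 2, data = fx$data))
  expect_equal(a$diff, b$diff)
})

test_that("IPW point estimate matches hand-computed weighted means on the fixture", {
  fx <- ipw_fixture()
  fit <- fit_response_propensity(fx$data)
  # the main-effects MLE reproduces the designed cell rates exactly
  expect_equal(sort(unique(round(fit$pi, 10))), c(0.25, 0.5))
  res <- ipw_difference(fx$data, fx$y, fit)
  expect_equal(res$diff, ipw_fixture_truth())
})

test_that("sandwich SE agrees with a delete-one jackknife oracle", {
  fx <- ipw_fixture(mult = 4)
  fit <- fit_response_propensity(fx$data)
  res <- ipw_difference(fx$data, fx$y, fit)
  se_jk <- ipw_jackknife_se(fx$data, fx$y)
  expect_lt(abs(res$se - se_jk) / se_jk, 0.15)
})

test_that("non-finite weights are rejected", {
  fx <- ipw_fixture()
  expect_error(propensity_fit(rep(0, nrow(fx$data)), data = fx$data),
               "probabilities")
})

test_that("imputation leaves observed values untouched and collapses with no missing", {
  trial <- generate_trial(simple_config(n_per_arm = 120), seed = 3)
  y <- outcome_vector(trial)
  imp <- impute_outcomes(trial, y, m = 5, seed = 2)
  expect_equal(dim(imp$copies), c(length(y), 5))
  obs <- !is.na(y)
  for (j in 1:5) expect_equal(imp$copies[obs, j], y[obs])
  # no missing at all: copies identical regardless of delta
  y_full <- ifelse(is.na(y), 50, y)
  imp_full <- impute_outcomes(trial, y_full, m = 3, seed = 2,
                              delta = c(3, -3))
  expect_equal(imp_full$copies, matrix(rep(y_full, 3), ncol = 3))
})

test_that("the delta shift is exactly additive under common random numbers", {
  trial <- generate_trial(simple_config(n_per_arm = 150), seed = 7)
  y <- outcome_vector(trial)
  i0 <- impute_outcomes(trial, y, m = 4, seed = 5, delta = c(0, 0))
  i1 <- impute_outcomes(trial, y, m = 4, seed = 5, delta = c(0, -2.5))
  d <- i1$copies - i0$copies
  mob_mis <- is.na(y) & trial$patients$arm == "mobile_web"
  tel_mis <- is.na(y) & trial$patients$arm == "telephone"
  expect_equal(unname(d[mob_mis, ]), matrix(-2.5, sum(mob_mis), 4))
  expect_true(all(d[tel_mis, ] == 0))
  expect_true(all(d[!is.na(y), ] == 0))
})

test_that("pooled imputed arm means track the complete-data means under MAR", {
  trial <- generate_trial(simple_config(n_per_arm = 1500), seed = 17)
  y <- outcome_vector(trial)
  df <- trial$patients
  imp <- impute_outcomes(trial, y, m = 20, seed = 8)
  for (a in c("telephone", "mobile_web")) {
    sel <- df$arm == a
    pooled <- mean(colMeans(imp$copies[sel, ]))
    # complete-data benchmark: observed scores + latent truth of nonrespondents
    bench <- mean(ifelse(is.na(y[sel]), trial$latent[sel], y[sel]))
    se <- stats::sd(trial$latent[sel]) / sqrt(sum(sel))
    expect_lt(abs(pooled - bench), 4 * se)
  }
})

test_that("an arm with fewer respondents than parameters is rejected", {
  df <- make_patients(arm = rep(c("telephone", "mobile_web"), each = 6),
                      responded = c(rep(TRUE, 2), rep(FALSE, 4), rep(TRUE, 6)),
                      hospital = rep(c("A", "B", "C"), 4))
  y <- ifelse(df$responded, 70, NA)
  expect_error(impute_outcomes(df, y, m = 2, seed = 1), "telephone")
})

test_that("Rubin pooling matches the closed-form two-copy oracle", {
  res <- rubin_pool(c(1, 3), c(1, 1))
  expect_equal(res$diff, 2)
  expect_equal(res$within, 1)
  expect_equal(res$between, 2)
  expect_equal(res$se, 2)           # T = 1 + (3/2)*2 = 4
  expect_equal(res$df, (2 - 1) * (1 + 1 / ((1 + 1 / 2) * 2))^2)  # 16/9
  expect_equal(res$df, 16 / 9)
})

test_that("Rubin pooling is permutation invariant and handles degenerate cases", {
  set.seed(41)
  q <- stats::rnorm(8); v <- stats::runif(8, 0.5, 2)
  p <- sample(8)
  a <- rubin_pool(q, v); b <- rubin_pool(q[p], v[p])
  expect_equal(a$diff, b$diff)
  expect_equal(a$se, b$se)
  # all copies identical: B = 0, total variance = within
  same <- rubin_pool(rep(1.5, 4), rep(0.9, 4))
  expect_equal(same$diff, 1.5)
  expect_equal(same$se, sqrt(0.9))
  expect_equal(same$df, Inf)
  expect_error(rubin_pool(rep(1, 3), rep(0, 3)), "degenerate")
  expect_error(rubin_pool(1, 1), "m >= 2")
})

test_that("MI collapses to the all-patient unadjusted analysis with no missing", {
  df <- make_patients(arm = rep(c("telephone", "mobile_web"), each = 6),
                      responded = TRUE)
  set.seed(13)
  y <- round(stats::runif(12, 40, 100))
  mi <- mi_difference(df, y, m = 5, seed = 1)
  un <- unadjusted_difference(df, y)
  expect_equal(mi$diff, un$diff)
  expect_equal(mi$se, un$se)
})

test_that("MI estimates are stable across seeds relative to their pooled SE", {
  trial <- generate_trial(simple_config(n_per_arm = 1200), seed = 23)
  y <- outcome_vector(trial)
  a <- mi_difference(trial, y, m = 50, seed = 1)
  b <- mi_difference(trial, y, m = 50, seed = 2)
  expect_lt(abs(a$diff - b$diff), a$se)
})
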