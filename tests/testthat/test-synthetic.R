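test_that("same seed and config give identical datasets and output files", {
  cfg <- simple_config(n_per_arm = 60)
  t1 <- generate_trial(cfg, seed = 9)
  t2 <- generate_trial(cfg, seed = 9)
  expect_identical(t1$patients, t2$patients)
  expect_identical(t1$latent, t2$latent)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trial(t1, f1)
  write_trial(t2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  t3 <- generate_trial(cfg, seed = 10)
  expect_false(identical(t1$patients, t3$patients))
})

test_that("generated structure honors the randomization and item contracts", {
  cfg <- simple_config(n_per_arm = 150)
  trial <- generate_trial(cfg, seed = 2)
  df <- trial$patients
  expect_equal(as.vector(table(df$arm)), c(150L, 150L))
  # items present iff responded, within their legal ranges
  likert <- paste0("q", c(1:12, 14:19))
  for (q in likert) {
    expect_true(all(is.na(df[[q]][!df$responded])))
    expect_true(all(df[[q]][df$responded] %in% 1:4))
  }
  expect_true(all(df$q13[df$responded] %in% c("yes", "no")))
  expect_true(all(is.na(df$q13[!df$responded])))
  expect_true(all(df$q20[df$responded] %in% 0:10))
  expect_true(all(df$q21[df$responded] %in% 0:10))
  expect_true(all(trial$latent >= 0 & trial$latent <= 100))
})

test_that("degenerate response mechanism yields full response", {
  cfg <- simple_config(n_per_arm = 50, response_intercept = 30, response_arm = 0)
  trial <- generate_trial(cfg, seed = 1)
  expect_true(all(trial$patients$responded))
  expect_false(anyNA(trial$patients$q1))
})

test_that("null effect produces a respondent difference within Monte Carlo error of zero", {
  cfg <- simple_config(n_per_arm = 2000, arm_effect = 0)
  trial <- generate_trial(cfg, seed = 4)
  y <- outcome_vector(trial)
  res <- unadjusted_difference(trial, y)
  expect_lt(abs(res$diff), 3 * res$se)
})

test_that("invalid configurations are rejected", {
  expect_error(simple_config(n_per_arm = 0), "positive integer")
  expect_error(simple_config(sd = -1), "positive")
  cfg_bad <- simple_config()
  expect_error(
    trial_config(10, strata_probs = list(
      sex = c(female = 0.7, male = 0.7),
      age_group = cfg_bad$strata_probs$age_group,
      care_field = cfg_bad$strata_probs$care_field,
      hospital = cfg_bad$strata_probs$hospital),
      response = cfg_bad$response, outcome = cfg_bad$outcome),
    "sum to 1")
})

test_that("calibrated config reproduces the reference arm response rates", {
  cfg <- table1_margins_config(n_per_arm = 1600)
  expect_equal(expected_response_rate(cfg, "telephone"), 358 / 1600,
               tolerance = 1e-6)
  expect_equal(expected_response_rate(cfg, "mobile_web"), 520 / 1600,
               tolerance = 1e-6)
  trial <- generate_trial(cfg, seed = 20)
  df <- trial$patients
  r_tel <- mean(df$responded[df$arm == "telephone"])
  r_mob <- mean(df$responded[df$arm == "mobile_web"])
  # binomial sampling error at n = 1600
  expect_lt(abs(r_tel - 0.224), 3 * sqrt(0.224 * 0.776 / 1600))
  expect_lt(abs(r_mob - 0.325), 3 * sqrt(0.325 * 0.675 / 1600))
})

test_that("respondent and nonrespondent latent means agree under MAR within cells", {
  cfg <- simple_config(n_per_arm = 4000)
  trial <- generate_trial(cfg, seed = 6)
  df <- trial$patients
  sel <- df$arm == "telephone" & df$sex == "female" & df$age_group == "40-59" &
    df$care_field == "surgical_other" & df$hospital == "A"
  a <- trial$latent[sel & df$responded]
  b <- trial$latent[sel & !df$responded]
  se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 4 * se)
})

test_that("ground truth round-trips the generating parameters", {
  cfg <- simple_config(arm_effect = -4,
                       mnar_shift = c(telephone = 0, mobile_web = -2.5))
  trial <- generate_trial(cfg, seed = 3)
  gt <- ground_truth(trial)
  expect_equal(gt$delta, -4)
  expect_equal(gt$delta1, 0)
  expect_equal(gt$delta2, -2.5)
  expect_true(is.finite(gt$estimand))
})

test_that("real-data-shaped input without truth metadata is refused", {
  trial <- generate_trial(simple_config(n_per_arm = 30), seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(trial, path, sidecar = FALSE)
  back <- read_trial(path)
  expect_error(ground_truth(back), "synthetic")
  expect_error(ground_truth(data.frame(x = 1)), "synthetic")
})

test_that("write/read round-trip preserves the patient table and truth", {
  trial <- generate_trial(simple_config(n_per_arm = 40), seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(trial, path)
  back <- read_trial(path)
  expect_equal(back$patients$arm, trial$patients$arm)
  expect_equal(back$patients$responded, trial$patients$responded)
  expect_equal(back$patients$q13, trial$patients$q13)
  expect_equal(back$patients$q20, trial$patients$q20)
  expect_equal(ground_truth(back)$delta, ground_truth(trial)$delta)
})

test_that("arms are balanced on strata up to sampling error", {
  trial <- generate_trial(simple_config(n_per_arm = 2000), seed = 12)
  df <- trial$patients
  for (f in c("sex", "age_group", "care_field", "hospital")) {
    p <- stats::chisq.test(table(df$arm, df[[f]]))$p.value
    expect_gt(p, 1e-4)
  }
})

test_that("item synthesis is an unbiased discretization of the latent score", {
  set.seed(31)
  for (t in c(12.3, 50, 84.9)) {
    items <- pxamode:::.generate_items(rep(t, 3000))
    sc <- vapply(paste0("q", 1:21), function(q) {
      mean(rescale_item(q, items[[q]]))
    }, numeric(1))
    tot <- mean(sc)
    # MC error of the mean of 3000 totals is well under 0.5 points
    expect_lt(abs(tot - t), 0.5)
  }
})

test_that("censored normal moments match numerical integration", {
  for (par in list(c(85, 14), c(50, 30), c(97, 10), c(5, 8))) {
    mu <- par[1]; s <- par[2]
    m_num <- stats::integrate(function(x) x * stats::dnorm(x, mu, s), 0, 100)$value +
      100 * stats::pnorm(100, mu, s, lower.tail = FALSE)
    m2_num <- stats::integrate(function(x) x^2 * stats::dnorm(x, mu, s), 0, 100)$value +
      100^2 * stats::pnorm(100, mu, s, lower.tail = FALSE)
    expect_equal(pxamode:::.censored_mean(mu, s), m_num, tolerance = 1e-6)
    expect_equal(pxamode:::.censored_var(mu, s), m2_num - m_num^2,
                 tolerance = 1e-6)
  }
})

test_that("the population estimand reflects censoring and MNAR shifts", {
  cfg0 <- simple_config(arm_effect = -4)
  base <- true_effect(cfg0)
  # censoring at 100 attenuates the latent -4 towards zero
  expect_gt(base, -4)
  expect_lt(base, 0)
  cfg1 <- simple_config(arm_effect = -4,
                        mnar_shift = c(telephone = 0, mobile_web = -2.5))
  shift_resp <- true_effect(cfg1) - base
  f_mob <- 1 - expected_response_rate(cfg1, "mobile_web")
  expect_equal(shift_resp, -2.5 * f_mob, tolerance = 1e-10)
})
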