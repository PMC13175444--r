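# Descriptive tables, tests and the sample-size helper.

#' Chi-square test of response rates between modes
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2
#' table of mode by response.
#'
#' @param n_resp_tel,n_tel respondents and randomized, telephone arm.
#' @param n_resp_mob,n_mob respondents and randomized, mobile web arm.
#' @return list with `statistic` and `p_value`.
#' @export
#' @examples
#' chi_square_mode_response(358, 1600, 520, 1600)
chi_square_mode_response <- function(n_resp_tel, n_tel, n_resp_mob, n_mob) {
  counts <- c(n_resp_tel, n_tel, n_resp_mob, n_mob)
  if (any(!vapply(counts, .is_count, logical(1)))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (n_resp_tel > n_tel || n_resp_mob > n_mob) {
    stop("respondents cannot exceed randomized", call. = FALSE)
  }
  tab <- rbind(telephone = c(n_resp_tel, n_tel - n_resp_tel),
               mobile_web = c(n_resp_mob, n_mob - n_resp_mob))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("undefined test: zero margin in the 2x2 table", call. = FALSE)
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
}

#' Response-rate table by mode and participant characteristic
#'
#' Counts, percentages and tests of mode differences in response
#' rates, by each stratification characteristic and in total. Two test
#' variants are reported per characteristic: `p_level`, the 2x2
#' mode-by-response chi-square within each level, and `p_overall`, a
#' likelihood-ratio test of the arm-by-characteristic interaction in a
#' logistic response model (does the mode gap differ across levels).
#' Tests that are undefined (zero margin) are reported as `NA`.
#'
#' @param data a `trial_data` object or patient data.frame.
#' @param digits decimal places for the percentage columns.
#' @return data.frame with one row per characteristic level (plus the
#'   Total row): counts, percentages and test columns.
#' @export
response_rate_table <- function(data, digits = 1) {
  df <- .patients(data)
  lv <- .strata_levels()
  for (f in names(lv)) {
    if (anyNA(df[[f]]) || !all(as.character(df[[f]]) %in% lv[[f]])) {
      stop("unknown category value in ", f, call. = FALSE)
    }
  }
  pct <- function(r, n) ifelse(n > 0, round_half_away(100 * r / n, digits), NA)
  row_for <- function(characteristic, level, sel) {
    tel <- sel & df$arm == "telephone"
    mob <- sel & df$arm == "mobile_web"
    r_t <- sum(df$responded[tel]); n_t <- sum(tel)
    r_m <- sum(df$responded[mob]); n_m <- sum(mob)
    p_lv <- tryCatch(chi_square_mode_response(r_t, n_t, r_m, n_m)$p_value,
                     error = function(e) NA_real_)
    data.frame(
      characteristic = characteristic, level = level,
      all_respondents = r_t + r_m, all_randomized = n_t + n_m,
      all_pct = pct(r_t + r_m, n_t + n_m),
      tel_respondents = r_t, tel_randomized = n_t, tel_pct = pct(r_t, n_t),
      mob_respondents = r_m, mob_randomized = n_m, mob_pct = pct(r_m, n_m),
      p_level = p_lv, p_overall = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- row_for("total", "total", rep(TRUE, nrow(df)))
  for (f in names(lv)) {
    block <- do.call(rbind, lapply(lv[[f]], function(l)
      row_for(f, l, df[[f]] == l)))
    block$p_overall <- if (all(df$responded) || !any(df$responded)) {
      NA_real_
    } else {
      tryCatch(suppressWarnings({
        full <- stats::glm(stats::as.formula(paste("responded ~ arm *", f)),
                           data = df, family = stats::binomial())
        null <- stats::glm(stats::as.formula(paste("responded ~ arm +", f)),
                           data = df, family = stats::binomial())
        stats::anova(null, full, test = "LRT")[2, "Pr(>Chi)"]
      }), error = function(e) NA_real_)
    }
    out <- rbind(out, block)
  }
  rownames(out) <- NULL
  out
}

#' Required respondents per group for a two-sample t-test
#'
#' Smallest integer per-group sample size achieving the target power
#' for a two-sided two-sample t-test with equal group sizes, computed
#' by iterating the noncentral-t power formula (not the normal
#' approximation).
#'
#' @param difference mean difference to detect (points).
#' @param sd common standard deviation (points).
#' @param power target power.
#' @param alpha two-sided significance level.
#' @return integer respondents per group.
#' @export
#' @examples
#' required_sample_size(1, 2, 0.80, 0.05)  # 64
required_sample_size <- function(difference, sd, power = 0.80, alpha = 0.05) {
  if (difference == 0 || sd <= 0 || power <= 0 || power >= 1 ||
      alpha <= 0 || alpha >= 1) {
    stop("need difference != 0, sd > 0, power and alpha in (0, 1)", call. = FALSE)
  }
  es <- abs(difference) / sd
  power_at <- function(n) {
    df <- 2 * n - 2
    ncp <- es * sqrt(n / 2)
    tc <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
  }
  n <- 2
  while (power_at(n) < power) {
    n <- n + 1
    if (n > 1e7) stop("unattainable sample size", call. = FALSE)
  }
  as.integer(n)
}

#' Assemble the full mode-effect results table
#'
#' For each requested outcome: respondent arm means (SD) and the
#' unadjusted, IPW-adjusted and MI-adjusted differences with 95% CI
#' and p-value -- the structure of the main results table of a mode
#' experiment.
#'
#' @inheritParams unadjusted_difference
#' @param outcomes outcomes to analyze (default: total plus the six
#'   domains).
#' @param m imputations for the MI column.
#' @param seed seed for the MI draws.
#' @return data.frame with one row per outcome.
#' @export
results_table <- function(data, outcomes = c("total", names(pxa_domains())),
                          m = 50, seed = 1L) {
  df <- .patients(data)
  scores <- pxa_scores(data)
  fit <- fit_response_propensity(data)
  rows <- lapply(outcomes, function(oc) {
    y <- outcome_vector(data, oc, scores = scores)
    resp <- !is.na(y)
    y_t <- y[resp & df$arm == "telephone"]
    y_m <- y[resp & df$arm == "mobile_web"]
    un <- unadjusted_difference(data, y, outcome = oc)
    ip <- ipw_difference(data, y, fit = fit, outcome = oc)
    mi <- mi_difference(data, y, m = m, seed = seed, outcome = oc)
    data.frame(
      outcome = oc,
      telephone_mean = mean(y_t), telephone_sd = stats::sd(y_t),
      mobile_mean = mean(y_m), mobile_sd = stats::sd(y_m),
      unadj_diff = un$diff, unadj_lo = un$ci95[1], unadj_hi = un$ci95[2],
      unadj_p = un$p_value,
      ipw_diff = ip$diff, ipw_lo = ip$ci95[1], ipw_hi = ip$ci95[2],
      ipw_p = ip$p_value,
      mi_diff = mi$diff, mi_lo = mi$ci95[1], mi_hi = mi$ci95[2],
      mi_p = mi$p_value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a results table for display
#'
#' Two-decimal formatting (round half away from zero) of the numeric
#' results of [results_table()], with `mean (SD)` and
#' `diff (lo to hi)` columns.
#'
#' @param tab result of [results_table()].
#' @return character data.frame.
#' @export
format_results_table <- function(tab) {
  f2 <- function(x) sprintf("%.2f", round_half_away(x, 2))
  data.frame(
    outcome = tab$outcome,
    telephone = paste0(f2(tab$telephone_mean), " (", f2(tab$telephone_sd), ")"),
    mobile_web = paste0(f2(tab$mobile_mean), " (", f2(tab$mobile_sd), ")"),
    unadjusted = paste0(f2(tab$unadj_diff), " (", f2(tab$unadj_lo), " to ",
                        f2(tab$unadj_hi), ")"),
    ipw = paste0(f2(tab$ipw_diff), " (", f2(tab$ipw_lo), " to ",
                 f2(tab$ipw_hi), ")"),
    mi = paste0(f2(tab$mi_diff), " (", f2(tab$mi_lo), " to ",
                f2(tab$mi_hi), ")"),
    stringsAsFactors = FALSE
  )
}
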