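# Mode-effect estimators: unadjusted, IPW (Hajek + stacked sandwich).

#' Construct an estimate result
#'
#' Container for a mode-effect estimate (mobile web minus telephone):
#' point estimate, standard error, 95% CI, two-sided p-value, and the
#' reference distribution (t with `df` degrees of freedom, or normal
#' when `df = Inf`).
#'
#' @param outcome outcome name.
#' @param method one of `"unadjusted"`, `"ipw"`, `"mi"`.
#' @param diff point estimate in points (mobile web - telephone).
#' @param se standard error.
#' @param df degrees of freedom of the reference distribution
#'   (`Inf` for normal).
#' @param n_analyzed number of patients entering the analysis.
#' @param m number of imputations (MI only).
#' @return object of class `estimate_result`.
#' @export
estimate_result <- function(outcome, method, diff, se, df = Inf,
                            n_analyzed = NA_integer_, m = NA_integer_) {
  crit <- stats::qt(0.975, df = df)
  p <- 2 * stats::pt(-abs(diff / se), df = df)
  structure(
    list(outcome = outcome, method = method, diff = diff, se = se,
         ci95 = c(diff - crit * se, diff + crit * se),
         p_value = p, df = df,
         n_analyzed = n_analyzed, m = m),
    class = "estimate_result"
  )
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf("%s mode effect on %s (mobile web - telephone):\n",
              x$method, x$outcome))
  cat(sprintf("  %.2f points (95%% CI %.2f to %.2f), SE %.3f, p = %.4g, n = %s\n",
              x$diff, x$ci95[1], x$ci95[2], x$se, x$p_value, x$n_analyzed))
  invisible(x)
}

.patients <- function(data) {
  if (inherits(data, "trial_data")) data$patients else as.data.frame(data)
}

.check_outcome <- function(df, y) {
  if (length(y) != nrow(df)) {
    stop("outcome vector must have one entry per randomized patient", call. = FALSE)
  }
  if (any(df$responded & is.na(y))) {
    stop("respondents with missing outcome; score the dataset first", call. = FALSE)
  }
}

#' Unadjusted mode-effect difference
#'
#' Difference in respondent mean scores (mobile web minus telephone)
#' with Welch two-sample (unequal variance) inference.
#'
#' @param data a `trial_data` object or patient data.frame.
#' @param y outcome vector aligned to the randomized sample (`NA` for
#'   nonrespondents), see [outcome_vector()].
#' @param outcome outcome label carried into the result.
#' @return an [estimate_result()].
#' @export
unadjusted_difference <- function(data, y, outcome = "total") {
  df <- .patients(data)
  .check_outcome(df, y)
  resp <- df$responded & !is.na(y)
  y_tel <- y[resp & df$arm == "telephone"]
  y_mob <- y[resp & df$arm == "mobile_web"]
  if (length(y_tel) < 2 || length(y_mob) < 2) {
    stop("each arm needs at least 2 respondents", call. = FALSE)
  }
  tt <- stats::t.test(y_mob, y_tel)
  estimate_result(outcome, "unadjusted",
                  diff = unname(tt$estimate[1] - tt$estimate[2]),
                  se = tt$stderr, df = unname(tt$parameter),
                  n_analyzed = length(y_tel) + length(y_mob))
}

#' Fit the response propensity model
#'
#' Maximum-likelihood logistic regression of the response indicator on
#' arm and the four stratification factors (main effects,
#' reference-coded on the alphabetically first level). Factors with a
#' single observed level are dropped from the design. Returns fitted
#' response probabilities for every randomized patient and inverse
#' probability weights for respondents.
#'
#' @param data a `trial_data` object or patient data.frame.
#' @param per_arm fit separate models within each arm (no arm term)
#'   instead of the pooled main-effects model.
#' @return object of class `propensity_fit` with elements `model` (the
#'   glm fit, or a list of two for `per_arm`), `pi` (fitted
#'   probabilities, length n), `weights` (1/pi for respondents, `NA`
#'   otherwise), `coef`.
#' @export
fit_response_propensity <- function(data, per_arm = FALSE) {
  df <- .patients(data)
  if (all(df$responded) || !any(df$responded)) {
    stop("both response outcomes must be present to fit the propensity model",
         call. = FALSE)
  }
  # separation check: a stratum level whose randomized patients are all
  # respondents or all nonrespondents cannot be fit
  for (f in c("arm", .strata_vars)) {
    tab <- table(droplevels(df[[f]]), df$responded)
    bad <- rownames(tab)[tab[, 1] == 0 | tab[, 2] == 0]
    if (length(bad)) {
      stop("separation in propensity model: level '", bad[1], "' of ", f,
           " has all-or-none response", call. = FALSE)
    }
  }
  vars_used <- function(d) {
    v <- .strata_vars[vapply(.strata_vars, function(f)
      nlevels(droplevels(d[[f]])) > 1, logical(1))]
    v
  }
  fit_one <- function(d, with_arm) {
    v <- vars_used(d)
    if (with_arm && nlevels(droplevels(d$arm)) > 1) v <- c("arm", v)
    rhs <- if (length(v)) paste(v, collapse = " + ") else "1"
    fm <- stats::as.formula(paste("responded ~", rhs))
    fit <- stats::glm(fm, data = droplevels(d), family = stats::binomial())
    if (!fit$converged) stop("propensity model did not converge", call. = FALSE)
    if (anyNA(stats::coef(fit))) {
      stop("rank-deficient propensity design: ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
           call. = FALSE)
    }
    fit
  }
  if (per_arm) {
    pi <- rep(NA_real_, nrow(df))
    models <- list()
    for (a in levels(df$arm)) {
      sel <- df$arm == a
      models[[a]] <- fit_one(df[sel, , drop = FALSE], with_arm = FALSE)
      pi[sel] <- stats::predict(models[[a]], type = "response")
    }
    model <- models
    coef <- lapply(models, stats::coef)
  } else {
    model <- fit_one(df, with_arm = TRUE)
    pi <- unname(stats::fitted(model))
    coef <- stats::coef(model)
  }
  if (any(pi <= 1e-10 | pi >= 1 - 1e-10)) {
    stop("fitted response probabilities at the boundary (separation)",
         call. = FALSE)
  }
  propensity_fit(pi, data = df, model = model, coef = coef)
}

#' Construct a propensity fit from known probabilities
#'
#' Wraps externally supplied response probabilities (e.g. design-known
#' probabilities in tests or simulations) in the structure consumed by
#' [ipw_difference()]. With no model attached, the sandwich variance
#' treats the weights as known.
#'
#' @param pi response probability for every randomized patient.
#' @param data the patient data the probabilities refer to (optional).
#' @param model fitted glm (attached by [fit_response_propensity()]).
#' @param coef coefficients (attached by [fit_response_propensity()]).
#' @return object of class `propensity_fit`.
#' @export
propensity_fit <- function(pi, data = NULL, model = NULL, coef = NULL) {
  if (any(!is.finite(pi) | pi <= 0 | pi > 1)) {
    stop("response probabilities must lie in (0, 1]", call. = FALSE)
  }
  w <- 1 / pi
  if (!is.null(data)) w[!data$responded] <- NA_real_
  structure(list(model = model, coef = coef, pi = pi, weights = w),
            class = "propensity_fit")
}

#' IPW-adjusted mode-effect difference
#'
#' Hajek (normalized) inverse-probability-weighted contrast of arm
#' means: within each arm the respondent outcomes are weighted by the
#' inverse of their fitted response probability and normalized by the
#' weight total, so the respondent sample represents the full
#' randomized population under MAR. The variance is the stacked
#' M-estimation sandwich over the logistic score equations and the two
#' weighted-mean estimating equations, which accounts for the
#' uncertainty from estimating the weights; the CI and p-value use the
#' normal reference.
#'
#' @inheritParams unadjusted_difference
#' @param fit a `propensity_fit`; defaults to fitting the pooled
#'   main-effects model on `data`.
#' @return an [estimate_result()].
#' @export
ipw_difference <- function(data, y, fit = fit_response_propensity(data),
                           outcome = "total") {
  df <- .patients(data)
  .check_outcome(df, y)
  if (length(fit$pi) != nrow(df)) {
    stop("propensity fit does not match the dataset", call. = FALSE)
  }
  r <- as.numeric(df$responded)
  w <- 1 / fit$pi
  if (any(!is.finite(w[r == 1]))) stop("non-finite weights", call. = FALSE)
  y0 <- ifelse(r == 1, y, 0)
  tel <- as.numeric(df$arm == "telephone")
  mob <- as.numeric(df$arm == "mobile_web")
  if (sum(r * tel) < 2 || sum(r * mob) < 2) {
    stop("each arm needs at least 2 respondents", call. = FALSE)
  }
  mu_t <- sum(r * tel * w * y0) / sum(r * tel * w)
  mu_m <- sum(r * mob * w * y0) / sum(r * mob * w)
  diff <- mu_m - mu_t

  n <- nrow(df)
  pi <- fit$pi
  glm_model <- if (!is.null(fit$model) && inherits(fit$model, "glm")) fit$model else NULL
  if (!is.null(glm_model)) {
    X <- stats::model.matrix(glm_model)
    k <- ncol(X)
  } else {
    X <- matrix(0, n, 0)
    k <- 0L
  }
  # stacked estimating equations: psi = (logistic score; Hajek means)
  psi_t <- tel * r * w * (y0 - mu_t)
  psi_m <- mob * r * w * (y0 - mu_m)
  Psi <- cbind(X * (r - pi), psi_t, psi_m)
  B <- crossprod(Psi) / n
  A <- matrix(0, k + 2, k + 2)
  if (k > 0) {
    A[1:k, 1:k] <- crossprod(X * (pi * (1 - pi)), X) / n
    A[k + 1, 1:k] <- colSums((tel * r * (y0 - mu_t) * (1 - pi) / pi) * X) / n
    A[k + 2, 1:k] <- colSums((mob * r * (y0 - mu_m) * (1 - pi) / pi) * X) / n
  }
  A[k + 1, k + 1] <- mean(tel * r * w)
  A[k + 2, k + 2] <- mean(mob * r * w)
  Ainv <- solve(A)
  V <- Ainv %*% B %*% t(Ainv) / n
  v_diff <- V[k + 1, k + 1] + V[k + 2, k + 2] - 2 * V[k + 1, k + 2]
  estimate_result(outcome, "ipw", diff = diff, se = sqrt(v_diff), df = Inf,
                  n_analyzed = n)
}
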