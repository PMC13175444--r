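# Multiple imputation by Bayesian linear regression, delta adjustment,
# and Rubin's rules.

#' Impute missing outcomes by Bayesian linear regression
#'
#' Within each arm separately, fits a linear regression of the observed
#' outcome on the four stratification factors (main effects) and, for
#' each of `m` copies, draws the residual variance from its scaled
#' inverse-chi-square posterior and the coefficients from their
#' conditional Gaussian posterior (noninformative prior), then imputes
#' each missing outcome as a posterior-predictive draw. The arm's
#' delta (`delta[1]` telephone, `delta[2]` mobile web) is added to
#' every imputed value afterwards, so for a fixed `seed` the underlying
#' random draws are identical across delta pairs (common random
#' numbers) and the delta acts as an exact additive shift. Imputed
#' values are not clipped to \[0, 100\] unless `clip = TRUE` (clipping
#' would break the additive-shift identity used for validation).
#'
#' @inheritParams unadjusted_difference
#' @param m number of imputed copies (>= 2).
#' @param delta numeric length-2 MNAR shift in points,
#'   `c(telephone, mobile_web)`; `c(0, 0)` is MAR.
#' @param seed RNG seed for the imputation draws.
#' @param clip clip imputed values to \[0, 100\].
#' @return object of class `imputed_set`: list with `copies` (n x m
#'   matrix of completed outcomes), `missing` (logical), `m`, `delta`,
#'   `seed`.
#' @export
impute_outcomes <- function(data, y, m = 50, delta = c(0, 0), seed = 1L,
                            clip = FALSE) {
  df <- .patients(data)
  .check_outcome(df, y)
  if (!.is_count(m) || m < 2) stop("m must be an integer >= 2", call. = FALSE)
  if (length(delta) != 2 || anyNA(delta)) {
    stop("delta must be c(telephone, mobile_web)", call. = FALSE)
  }
  miss <- is.na(y)
  copies <- matrix(rep(y, m), ncol = m)
  if (any(miss)) {
    set.seed(.child_seed(seed, 11))
    arm_delta <- c(telephone = delta[1], mobile_web = delta[2])
    for (a in c("telephone", "mobile_web")) {
      sel <- df$arm == a
      obs <- sel & !miss
      mis <- sel & miss
      if (!any(mis)) next
      if (!any(obs)) stop("no respondents in arm ", a, call. = FALSE)
      d_arm <- droplevels(df[sel, , drop = FALSE])
      v <- .strata_vars[vapply(.strata_vars, function(f)
        nlevels(d_arm[[f]]) > 1, logical(1))]
      fml <- stats::as.formula(
        paste("~", if (length(v)) paste(v, collapse = " + ") else "1"))
      Xall <- stats::model.matrix(fml, d_arm)
      X <- Xall[!miss[sel], , drop = FALSE]
      Xm <- Xall[miss[sel], , drop = FALSE]
      yobs <- y[obs]
      k <- ncol(X)
      if (nrow(X) <= k) {
        stop("fewer respondents than regression parameters in arm ", a,
             call. = FALSE)
      }
      qrX <- qr(X)
      if (qrX$rank < k) {
        stop("rank-deficient imputation design in arm ", a,
             " (a stratum level has no respondents)", call. = FALSE)
      }
      beta_hat <- qr.coef(qrX, yobs)
      res <- yobs - drop(X %*% beta_hat)
      nu <- nrow(X) - k
      rss <- sum(res^2)
      Rinv <- backsolve(qr.R(qrX), diag(k))   # (X'X)^{-1} = Rinv Rinv'
      for (j in seq_len(m)) {
        sigma2 <- rss / stats::rchisq(1, nu)
        beta <- beta_hat + sqrt(sigma2) * drop(Rinv %*% stats::rnorm(k))
        pred <- drop(Xm %*% beta) + stats::rnorm(nrow(Xm), 0, sqrt(sigma2))
        imp <- pred + arm_delta[[a]]
        if (clip) imp <- pmin(pmax(imp, 0), 100)
        copies[mis, j] <- imp
      }
    }
  }
  structure(list(copies = copies, missing = miss, m = as.integer(m),
                 delta = delta, seed = seed, clip = clip),
            class = "imputed_set")
}

#' Pool per-copy estimates with Rubin's rules
#'
#' Combines `m` per-copy point estimates and squared standard errors:
#' the pooled estimate is the mean `Qbar`; the total variance is
#' `T = W + (1 + 1/m) B` with `W` the mean within-imputation variance
#' and `B` the between-imputation variance (divisor `m - 1`); the
#' reference distribution is t with the classical degrees of freedom
#' `df = (m - 1) (1 + W / ((1 + 1/m) B))^2`.
#'
#' @param estimates per-copy point estimates.
#' @param variances per-copy squared standard errors.
#' @param outcome outcome label.
#' @param n_analyzed number analyzed, carried into the result.
#' @return an [estimate_result()] with method `"mi"`.
#' @export
rubin_pool <- function(estimates, variances, outcome = "total",
                       n_analyzed = NA_integer_) {
  m <- length(estimates)
  if (m < 2 || length(variances) != m) {
    stop("need m >= 2 matching-length estimates and variances", call. = FALSE)
  }
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- stats::var(estimates)
  total <- w + (1 + 1 / m) * b
  if (b == 0) {
    if (w == 0) stop("degenerate pooled variance (W = B = 0)", call. = FALSE)
    df <- Inf
  } else {
    df <- (m - 1) * (1 + w / ((1 + 1 / m) * b))^2
  }
  out <- estimate_result(outcome, "mi", diff = qbar, se = sqrt(total),
                         df = df, n_analyzed = n_analyzed, m = m)
  out$within <- w
  out$between <- b
  out
}

#' MI-adjusted mode-effect difference
#'
#' Multiple-imputation estimate of the mode effect: missing outcomes of
#' nonrespondents are imputed by [impute_outcomes()]; on each completed
#' copy the unweighted arm-mean difference (mobile web minus telephone)
#' over all randomized patients is computed with its Welch variance;
#' the copies are pooled with [rubin_pool()]. `delta = c(0, 0)` (the
#' default) is the MAR analysis; nonzero delta gives the
#' delta-adjusted pattern-mixture estimate.
#'
#' @inheritParams impute_outcomes
#' @param outcome outcome label.
#' @return an [estimate_result()] with method `"mi"`.
#' @export
mi_difference <- function(data, y, m = 50, seed = 1L, delta = c(0, 0),
                          outcome = "total", clip = FALSE) {
  df <- .patients(data)
  imp <- impute_outcomes(data, y, m = m, delta = delta, seed = seed, clip = clip)
  tel <- df$arm == "telephone"
  mob <- df$arm == "mobile_web"
  n_t <- sum(tel); n_m <- sum(mob)
  est <- numeric(m); v <- numeric(m)
  for (j in seq_len(m)) {
    yc <- imp$copies[, j]
    est[j] <- mean(yc[mob]) - mean(yc[tel])
    v[j] <- stats::var(yc[mob]) / n_m + stats::var(yc[tel]) / n_t
  }
  if (!any(imp$missing)) {
    # nothing imputed: collapse to the complete-data analysis
    tt <- stats::t.test(y[mob], y[tel])
    out <- estimate_result(outcome, "mi",
                           diff = unname(tt$estimate[1] - tt$estimate[2]),
                           se = tt$stderr, df = unname(tt$parameter),
                           n_analyzed = n_t + n_m, m = m)
    return(out)
  }
  rubin_pool(est, v, outcome = outcome, n_analyzed = n_t + n_m)
}
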