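# Subgroup mode effects and interaction tests.

# Multivariate Rubin pooling (D1 statistic) for a k-vector of
# interaction contrasts estimated on each imputed copy.
.pool_wald <- function(qs, us) {
  m <- length(qs)
  k <- length(qs[[1]])
  qbar <- Reduce(`+`, qs) / m
  ubar <- Reduce(`+`, us) / m
  bmat <- matrix(0, k, k)
  for (j in seq_len(m)) {
    d <- qs[[j]] - qbar
    bmat <- bmat + tcrossprod(d)
  }
  bmat <- bmat / (m - 1)
  r <- (1 + 1 / m) * sum(diag(bmat %*% solve(ubar))) / k
  if (!is.finite(r) || r < 1e-12) {
    # no between-imputation variability: plain Wald chi-square
    w <- drop(t(qbar) %*% solve(ubar) %*% qbar)
    return(stats::pchisq(w, df = k, lower.tail = FALSE))
  }
  d1 <- drop(t(qbar) %*% solve(ubar) %*% qbar) / (k * (1 + r))
  nu <- k * (m - 1)
  df2 <- if (nu > 4) {
    4 + (nu - 4) * (1 + (1 - 2 / nu) / r)^2
  } else {
    nu * (1 + 1 / k) * (1 + 1 / r)^2 / 2
  }
  stats::pf(d1, k, df2, lower.tail = FALSE)
}

# Wald chi-square p-value for the interaction coefficients of a fitted
# linear model with covariance V.
.wald_interaction <- function(fit, V, pattern = ":") {
  idx <- grep(pattern, names(stats::coef(fit)), fixed = TRUE)
  b <- stats::coef(fit)[idx]
  Vi <- V[idx, idx, drop = FALSE]
  w <- drop(t(b) %*% solve(Vi) %*% b)
  stats::pchisq(w, df = length(b), lower.tail = FALSE)
}

#' Subgroup mode effects with interaction tests
#'
#' Re-runs the mode-effect analyses within each level of a subgroup
#' variable and tests whether the effect differs across levels.
#' Per-level estimates restrict the data to the level (the propensity
#' and imputation models are refit within it). Interaction p-values
#' come from a Wald test of the arm-by-variable terms in a linear
#' model of the outcome: unweighted on respondents (`unadjusted`),
#' IPW-weighted with an HC0 sandwich covariance (`ipw`), or fit on
#' each imputed copy and pooled with the multivariate Rubin rules
#' (`mi`).
#'
#' @inheritParams unadjusted_difference
#' @param variable subgroup variable: `"sex"`, `"age_group"` or
#'   `"care_field"`.
#' @param methods subset of `c("unadjusted", "ipw", "mi")`.
#' @param m imputations for the MI method.
#' @param seed seed for the MI draws.
#' @return list with `variable`, `estimates` (data.frame of per-level
#'   results by method) and `interaction_p` (named by method).
#' @export
subgroup_analysis <- function(data, y, variable = c("sex", "age_group", "care_field"),
                              methods = c("unadjusted", "ipw", "mi"),
                              m = 20, seed = 1L, outcome = "total") {
  variable <- match.arg(variable)
  methods <- match.arg(methods, several.ok = TRUE)
  df <- .patients(data)
  .check_outcome(df, y)
  v <- droplevels(df[[variable]])
  if (nlevels(v) < 2) {
    stop("interaction test undefined: ", variable, " has a single level",
         call. = FALSE)
  }
  for (l in levels(v)) {
    for (a in .arm_levels) {
      if (!any(df$responded & v == l & df$arm == a)) {
        stop("no respondents in cell ", variable, "=", l, " x arm=", a,
             call. = FALSE)
      }
    }
  }

  est_rows <- list()
  for (l in levels(v)) {
    sel <- v == l
    sub <- df[sel, , drop = FALSE]
    ysub <- y[sel]
    for (meth in methods) {
      r <- switch(meth,
        unadjusted = unadjusted_difference(sub, ysub, outcome = outcome),
        ipw = ipw_difference(sub, ysub, fit = fit_response_propensity(sub),
                             outcome = outcome),
        mi = mi_difference(sub, ysub, m = m, seed = seed, outcome = outcome)
      )
      est_rows[[length(est_rows) + 1]] <- data.frame(
        level = l, method = meth, diff = r$diff, se = r$se,
        ci_low = r$ci95[1], ci_high = r$ci95[2], p = r$p_value,
        n = r$n_analyzed, stringsAsFactors = FALSE
      )
    }
  }

  interaction_p <- c()
  dat <- df
  dat$.y <- y
  dat$.v <- v
  if ("unadjusted" %in% methods) {
    rsp <- dat[dat$responded, , drop = FALSE]
    full <- stats::lm(.y ~ arm * .v, data = rsp)
    null <- stats::lm(.y ~ arm + .v, data = rsp)
    interaction_p["unadjusted"] <- stats::anova(null, full)[2, "Pr(>F)"]
  }
  if ("ipw" %in% methods) {
    fit <- fit_response_propensity(df)
    rsp <- dat[dat$responded, , drop = FALSE]
    rsp$.w <- fit$weights[dat$responded]
    wfit <- stats::lm(.y ~ arm * .v, data = rsp, weights = .w)
    V <- sandwich::vcovHC(wfit, type = "HC0")
    interaction_p["ipw"] <- .wald_interaction(wfit, V)
  }
  if ("mi" %in% methods) {
    imp <- impute_outcomes(df, y, m = m, seed = seed)
    qs <- list(); us <- list()
    for (j in seq_len(m)) {
      dat$.yc <- imp$copies[, j]
      cfit <- stats::lm(.yc ~ arm * .v, data = dat)
      idx <- grep(":", names(stats::coef(cfit)), fixed = TRUE)
      qs[[j]] <- stats::coef(cfit)[idx]
      us[[j]] <- stats::vcov(cfit)[idx, idx, drop = FALSE]
    }
    interaction_p["mi"] <- .pool_wald(qs, us)
  }

  list(variable = variable,
       estimates = do.call(rbind, est_rows),
       interaction_p = interaction_p)
}
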