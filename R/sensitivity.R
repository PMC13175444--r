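# Delta-adjustment pattern-mixture sensitivity analysis.

#' Delta-adjustment scenario grid
#'
#' Recomputes the MI-adjusted mode effect over a grid of pattern-
#' mixture shifts: for each pair (delta1, delta2), nonrespondents'
#' imputed outcomes in the telephone and mobile web arms are shifted by
#' delta1 and delta2 points respectively before pooling. All cells use
#' the same seed, hence common random numbers: with no clipping the
#' estimates obey the exact identity
#' `diff(d1, d2) = diff(0, 0) + d2 * f_mob - d1 * f_tel`, where `f_arm`
#' is the arm's missing fraction, so the grid isolates the delta effect
#' from Monte Carlo noise. `(0, 0)` coincides with the MAR MI analysis.
#'
#' @inheritParams mi_difference
#' @param delta1_values ordered shifts (points) for telephone
#'   nonrespondents.
#' @param delta2_values ordered shifts (points) for mobile web
#'   nonrespondents.
#' @param window plausibility window for the shifts; values outside it
#'   are rejected.
#' @return object of class `scenario_grid`: list with `delta1`,
#'   `delta2`, `results` (list-matrix of [estimate_result()]s indexed
#'   `[delta1, delta2]`), `f_tel`, `f_mob` (missing fractions), `m`,
#'   `seed`. Use [as.data.frame()] for a long-format table.
#' @export
#' @examples
#' cfg <- table1_margins_config(n_per_arm = 150)
#' trial <- generate_trial(cfg, seed = 3)
#' y <- outcome_vector(trial)
#' g <- delta_grid(trial, y, m = 5, seed = 3)
#' head(as.data.frame(g))
delta_grid <- function(data, y,
                       delta1_values = seq(-5, 5, by = 2.5),
                       delta2_values = seq(-5, 5, by = 2.5),
                       m = 50, seed = 1L, outcome = "total",
                       window = c(-10, 10)) {
  if (!length(delta1_values) || !length(delta2_values)) {
    stop("delta value lists must be nonempty", call. = FALSE)
  }
  if (any(c(delta1_values, delta2_values) < window[1]) ||
      any(c(delta1_values, delta2_values) > window[2])) {
    stop("delta values outside the plausibility window [",
         window[1], ", ", window[2], "]", call. = FALSE)
  }
  df <- .patients(data)
  miss <- is.na(y)
  f_arm <- function(a) mean(miss[df$arm == a])
  results <- matrix(vector("list", length(delta1_values) * length(delta2_values)),
                    nrow = length(delta1_values),
                    dimnames = list(format(delta1_values), format(delta2_values)))
  for (i in seq_along(delta1_values)) {
    for (j in seq_along(delta2_values)) {
      res <- tryCatch(
        mi_difference(data, y, m = m, seed = seed,
                      delta = c(delta1_values[i], delta2_values[j]),
                      outcome = outcome),
        error = function(e) {
          stop("delta grid failed at cell (", delta1_values[i], ", ",
               delta2_values[j], "): ", conditionMessage(e), call. = FALSE)
        }
      )
      results[[i, j]] <- res
    }
  }
  structure(
    list(delta1 = delta1_values, delta2 = delta2_values, results = results,
         f_tel = f_arm("telephone"), f_mob = f_arm("mobile_web"),
         m = m, seed = seed, outcome = outcome),
    class = "scenario_grid"
  )
}

#' @export
as.data.frame.scenario_grid <- function(x, ...) {
  rows <- list()
  for (i in seq_along(x$delta1)) {
    for (j in seq_along(x$delta2)) {
      r <- x$results[[i, j]]
      rows[[length(rows) + 1]] <- data.frame(
        delta1 = x$delta1[i], delta2 = x$delta2[j],
        diff = r$diff, se = r$se,
        ci_low = r$ci95[1], ci_high = r$ci95[2], p = r$p_value
      )
    }
  }
  do.call(rbind, rows)
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat(sprintf("Delta-adjustment grid for '%s' (m = %d, seed = %s)\n",
              x$outcome, x$m, format(x$seed)))
  est <- matrix(vapply(x$results, function(r) r$diff, numeric(1)),
                nrow = length(x$delta1),
                dimnames = list(paste0("d1=", format(x$delta1)),
                                paste0("d2=", format(x$delta2))))
  print(round(est, 2))
  invisible(x)
}

#' Locate tipping points of a scenario grid
#'
#' Scans the grid for adjacent cells where the estimate changes sign,
#' and separately where the "95% CI excludes 0" status changes. For
#' sign changes the exact crossing along the axis is interpolated from
#' the linear-in-delta identity (exact under common random numbers and
#' no clipping).
#'
#' @param grid a [delta_grid()] result.
#' @return list with data.frames `sign` (columns `axis`, `fixed`,
#'   `lower`, `upper`, `crossing`) and `significance` (columns `axis`,
#'   `fixed`, `lower`, `upper`); either may have zero rows.
#' @export
tipping_boundary <- function(grid) {
  stopifnot(inherits(grid, "scenario_grid"))
  est <- matrix(vapply(grid$results, function(r) r$diff, numeric(1)),
                nrow = length(grid$delta1))
  excl <- matrix(vapply(grid$results, function(r)
    r$ci95[1] > 0 || r$ci95[2] < 0, logical(1)),
    nrow = length(grid$delta1))
  # intercept of the linear surface diff = C - d1 * f_tel + d2 * f_mob
  C <- est[1, 1] + grid$delta1[1] * grid$f_tel - grid$delta2[1] * grid$f_mob

  sign_rows <- list(); sig_rows <- list()
  add_sign <- function(axis, fixed, lo, hi, crossing) {
    sign_rows[[length(sign_rows) + 1]] <<- data.frame(
      axis = axis, fixed = fixed, lower = lo, upper = hi, crossing = crossing)
  }
  add_sig <- function(axis, fixed, lo, hi) {
    sig_rows[[length(sig_rows) + 1]] <<- data.frame(
      axis = axis, fixed = fixed, lower = lo, upper = hi)
  }
  d1 <- grid$delta1; d2 <- grid$delta2
  for (i in seq_along(d1)) {
    for (j in seq_len(length(d2) - 1)) {
      if (sign(est[i, j]) != sign(est[i, j + 1]) &&
          (est[i, j] != 0 || est[i, j + 1] != 0)) {
        cross <- (d1[i] * grid$f_tel - C) / grid$f_mob
        add_sign("delta2", d1[i], d2[j], d2[j + 1], cross)
      }
      if (excl[i, j] != excl[i, j + 1]) add_sig("delta2", d1[i], d2[j], d2[j + 1])
    }
  }
  for (j in seq_along(d2)) {
    for (i in seq_len(length(d1) - 1)) {
      if (sign(est[i, j]) != sign(est[i + 1, j]) &&
          (est[i, j] != 0 || est[i + 1, j] != 0)) {
        cross <- (C + d2[j] * grid$f_mob) / grid$f_tel
        add_sign("delta1", d2[j], d1[i], d1[i + 1], cross)
      }
      if (excl[i, j] != excl[i + 1, j]) add_sig("delta1", d2[j], d1[i], d1[i + 1])
    }
  }
  empty_sign <- data.frame(axis = character(), fixed = numeric(),
                           lower = numeric(), upper = numeric(),
                           crossing = numeric())
  empty_sig <- empty_sign[, 1:4]
  list(sign = if (length(sign_rows)) do.call(rbind, sign_rows) else empty_sign,
       significance = if (length(sig_rows)) do.call(rbind, sig_rows) else empty_sig)
}
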