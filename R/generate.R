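# Synthetic two-arm mode experiment generator with known ground truth.

# Stochastic rounding of targets t (in [0,100]) to a grid of `k` equal
# steps spanning 0..100; returns the grid index 0..k. Unbiased:
# E[step * index] = t.
.stochastic_round <- function(t, k) {
  s <- 100 / k
  lo <- floor(t / s)
  f <- t / s - lo
  pmin(lo + (stats::runif(length(t)) < f), k)
}

# Generate raw item responses whose computed total is an unbiased,
# discretized realization of the latent total t (one row per respondent).
.generate_items <- function(t) {
  n <- length(t)
  it <- pxa_items()
  out <- vector("list", 21)
  names(out) <- it$item
  for (j in seq_len(21)) {
    out[[j]] <- switch(it$type[j],
      likert = .stochastic_round(t, 3L) + 1L,
      binary = ifelse(stats::runif(n) < t / 100, "yes", "no"),
      rating = .stochastic_round(t, 10L)
    )
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Generate a synthetic randomized mode experiment
#'
#' Draws `n_per_arm` patients per arm with strata sampled independently
#' from the configured margins, a latent 0-100 outcome (linear
#' predictor plus Gaussian noise, censored to \[0, 100\]), response
#' from the main-effects logistic model, and -- for respondents -- 21
#' raw item responses whose rescaled total is an unbiased discretized
#' realization of the latent score. Nonrespondents' latent outcomes are
#' shifted by the arm's MNAR delta (and carry no observable items).
#' The generating parameters are retained for validation via
#' [ground_truth()].
#'
#' @param config a [trial_config()], e.g. [table1_margins_config()].
#' @param seed master seed; defaults to `config$seed`. Stage-level
#'   child streams (strata, outcome, response, items) are derived
#'   deterministically from it.
#' @return an object of class `trial_data`: a list with `patients`
#'   (one row per randomized patient: `patient_id`, `arm`, the four
#'   strata, `responded`, `q1`..`q21` with `NA` for nonrespondents),
#'   `latent` (hidden latent totals, post-MNAR-shift), `config`, and
#'   `truth`.
#' @export
#' @examples
#' cfg <- table1_margins_config(n_per_arm = 200)
#' trial <- generate_trial(cfg, seed = 7)
#' table(trial$patients$arm, trial$patients$responded)
generate_trial <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "trial_config"))
  n <- config$n_per_arm
  N <- 2L * n
  lv <- .strata_levels()

  arm <- factor(rep(c("telephone", "mobile_web"), each = n), levels = .arm_levels)

  set.seed(.child_seed(seed, 1))
  df <- data.frame(
    patient_id = sprintf("P%05d", seq_len(N)),
    arm = arm, stringsAsFactors = FALSE
  )
  for (f in names(lv)) {
    p <- config$strata_probs[[f]]
    df[[f]] <- factor(sample(lv[[f]], N, replace = TRUE, prob = p), levels = lv[[f]])
  }

  lin <- function(coefs, intercept, arm_term) {
    e <- rep(intercept, N) + ifelse(df$arm == "mobile_web", arm_term, 0)
    for (f in names(lv)) {
      cf <- coefs[[f]]
      if (!is.null(cf) && length(cf)) {
        hit <- match(as.character(df[[f]]), names(cf))
        e <- e + ifelse(is.na(hit), 0, cf[hit])
      }
    }
    e
  }

  set.seed(.child_seed(seed, 2))
  mu <- lin(config$outcome, config$outcome$intercept, config$outcome$arm_effect)
  sd_i <- config$outcome$sd[as.character(df$arm)]
  latent <- pmin(pmax(mu + stats::rnorm(N, 0, sd_i), 0), 100)

  set.seed(.child_seed(seed, 3))
  pi <- stats::plogis(lin(config$response, config$response$intercept,
                          config$response$arm))
  df$responded <- stats::runif(N) < pi

  # MNAR: shift nonrespondents' latent outcomes by the arm's delta
  shift <- config$mnar_shift[as.character(df$arm)]
  latent[!df$responded] <- latent[!df$responded] + shift[!df$responded]

  set.seed(.child_seed(seed, 4))
  items <- as.data.frame(
    matrix(NA, N, 21, dimnames = list(NULL, pxa_items()$item))
  )
  items$q13 <- NA_character_
  if (any(df$responded)) {
    gen <- .generate_items(latent[df$responded])
    for (j in names(gen)) items[[j]][df$responded] <- gen[[j]]
  }
  df <- cbind(df, items)
  rownames(df) <- NULL

  structure(
    list(patients = df,
         latent = latent,
         config = config,
         truth = list(delta = config$outcome$arm_effect,
                      delta1 = unname(config$mnar_shift[["telephone"]]),
                      delta2 = unname(config$mnar_shift[["mobile_web"]]),
                      estimand = true_effect(config))),
    class = "trial_data"
  )
}

#' @export
print.trial_data <- function(x, ...) {
  df <- x$patients
  cat("Synthetic mode-experiment dataset:", nrow(df), "randomized patients\n")
  tab <- table(df$arm, df$responded)
  print(tab)
  invisible(x)
}

#' Ground truth of a synthetic dataset
#'
#' Returns the generating parameters stored with a synthetic dataset:
#' the latent-scale mode effect `delta`, the MNAR shifts `delta1`
#' (telephone) and `delta2` (mobile web), and `estimand`, the implied
#' population mean-score contrast (see [true_effect()]) that the
#' adjusted estimators target.
#'
#' @param data a `trial_data` object produced by [generate_trial()].
#' @return list with `delta`, `delta1`, `delta2`, `estimand`.
#' @export
ground_truth <- function(data) {
  if (!inherits(data, "trial_data") || is.null(data$truth)) {
    stop("ground truth is only available for synthetic datasets ",
         "produced by generate_trial()", call. = FALSE)
  }
  data$truth
}

#' Write a trial dataset to delimited text
#'
#' Writes one row per randomized patient (`patient_id, arm, sex,
#' age_group, care_field, hospital, responded, q1..q21`; item cells
#' empty for nonrespondents) and, for synthetic data, a sidecar JSON
#' file `<path>.meta.json` holding the generating configuration and
#' truth values.
#'
#' @param data a `trial_data` object or patient data.frame.
#' @param path output CSV path.
#' @param sidecar write the metadata sidecar (default `TRUE` when
#'   generating metadata is present).
#' @return `path`, invisibly.
#' @export
write_trial <- function(data, path, sidecar = inherits(data, "trial_data")) {
  df <- if (inherits(data, "trial_data")) data$patients else as.data.frame(data)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (sidecar && inherits(data, "trial_data") && !is.null(data$config)) {
    meta <- list(config = unclass(data$config), truth = data$truth)
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a trial dataset from delimited text
#'
#' Restores the canonical factor codings. If the sidecar metadata file
#' written by [write_trial()] is present, the generating configuration
#' and truth are restored so that [ground_truth()] works; otherwise the
#' dataset is treated as real-data-shaped (no truth available).
#'
#' @param path CSV path written by [write_trial()] (or equivalent).
#' @return a `trial_data` object.
#' @export
read_trial <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(q13 = "character"))
  df$arm <- factor(df$arm, levels = .arm_levels)
  lv <- .strata_levels()
  for (f in names(lv)) df[[f]] <- factor(df[[f]], levels = lv[[f]])
  df$responded <- as.logical(df$responded)
  df$q13[!is.na(df$q13) & df$q13 == ""] <- NA_character_
  bad <- is.na(df$arm) | Reduce(`|`, lapply(names(lv), function(f) is.na(df[[f]])))
  if (any(bad)) stop("unknown arm or stratum value in rows: ",
                     paste(utils::head(which(bad)), collapse = ", "), call. = FALSE)
  out <- list(patients = df, latent = NULL, config = NULL, truth = NULL)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    out$truth <- meta$truth
    out$config <- meta$config
  }
  structure(out, class = "trial_data")
}
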