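# Scoring of the 21-item PXA questionnaire on the 0-100 convention.

#' PXA item metadata
#'
#' The 21 items of the Korean Patient Experience Assessment, their
#' domain membership and response format. Items q1-q12 and q14-q19 use
#' a 4-point Likert scale (1-4), q13 is binary (`"yes"`/`"no"`), and
#' the two overall rating items q20-q21 use a 0-10 scale.
#'
#' @return a data.frame with columns `item`, `domain`, `type`.
#' @export
#' @examples
#' table(pxa_items()$domain)
pxa_items <- function() {
  data.frame(
    item = paste0("q", 1:21),
    domain = rep(
      c("nurse", "doctor", "medication_treatment", "hospital_environment",
        "patients_rights", "overall_rating"),
      times = c(4, 4, 5, 2, 4, 2)
    ),
    type = c(rep("likert", 12), "binary", rep("likert", 6),
             rep("rating", 2)),
    stringsAsFactors = FALSE
  )
}

#' Domain map of the PXA questionnaire
#'
#' @return named list mapping each of the six domains to its ordered items.
#' @export
pxa_domains <- function() {
  it <- pxa_items()
  split(it$item, factor(it$domain, levels = unique(it$domain)))
}

.item_type <- function(item_id) {
  it <- pxa_items()
  i <- match(item_id, it$item)
  if (is.na(i)) stop("unknown item: ", item_id, call. = FALSE)
  it$type[i]
}

#' Rescale a raw item response to 0-100 points
#'
#' Every item is rescaled so its maximum response is worth 100 points
#' and its minimum 0: Likert responses map 1, 2, 3, 4 to 0, 100/3,
#' 200/3, 100; the binary item maps `"yes"` to 100 and `"no"` to 0;
#' the 0-10 rating items map v to 10 v.
#'
#' @param item_id item identifier, e.g. `"q3"`.
#' @param raw vector of raw responses for that item.
#' @return numeric vector of item scores in \[0, 100\].
#' @export
#' @examples
#' rescale_item("q3", c(1, 2, 3, 4))
#' rescale_item("q13", c("yes", "no"))
#' rescale_item("q20", 0:10)
rescale_item <- function(item_id, raw) {
  type <- .item_type(item_id)
  bad_value <- function(v) {
    stop("invalid raw response for item ", item_id, ": ",
         paste(unique(v), collapse = ", "), call. = FALSE)
  }
  switch(type,
    likert = {
      r <- suppressWarnings(as.numeric(raw))
      ok <- !is.na(r) & r %in% 1:4
      if (!all(ok)) bad_value(raw[!ok])
      (r - 1) / 3 * 100
    },
    binary = {
      r <- as.character(raw)
      ok <- !is.na(r) & r %in% c("yes", "no")
      if (!all(ok)) bad_value(raw[!ok])
      ifelse(r == "yes", 100, 0)
    },
    rating = {
      r <- suppressWarnings(as.numeric(raw))
      ok <- !is.na(r) & r %in% 0:10
      if (!all(ok)) bad_value(raw[!ok])
      10 * r
    }
  )
}

# Coerce x (matrix/data.frame with item columns, or named vector for one
# respondent) to an n x 21 matrix of 0-100 item *scores*.
.as_score_matrix <- function(x) {
  items <- pxa_items()$item
  if (is.null(dim(x))) {
    if (is.null(names(x))) stop("item scores must be named q1..q21", call. = FALSE)
    x <- as.data.frame(as.list(x))
  }
  x <- as.data.frame(x)
  missing_cols <- setdiff(items, names(x))
  if (length(missing_cols)) {
    stop("missing item(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(x[, items, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    bad <- items[colSums(is.na(m)) > 0]
    stop("missing item score(s): ", paste(bad, collapse = ", "),
         "; partial scoring is not supported", call. = FALSE)
  }
  if (any(m < 0 | m > 100)) stop("item scores must lie in [0, 100]", call. = FALSE)
  m
}

#' Domain score
#'
#' A domain's score is the sum of its item scores rescaled so the
#' maximum is 100, i.e. the arithmetic mean of the 0-100 item scores.
#' No partial scoring: every item of the domain must be present.
#'
#' @param item_scores named vector, matrix or data.frame of 0-100 item
#'   scores with columns (or names) `q1`..`q21` (only the domain's items
#'   are required).
#' @param domain one of `names(pxa_domains())`.
#' @return numeric vector of domain scores, one per respondent.
#' @export
domain_score <- function(item_scores, domain) {
  dom <- pxa_domains()
  if (!domain %in% names(dom)) {
    stop("unknown domain: ", domain, call. = FALSE)
  }
  items <- dom[[domain]]
  if (is.null(dim(item_scores))) {
    item_scores <- as.data.frame(as.list(item_scores))
  }
  x <- as.data.frame(item_scores)
  missing_cols <- setdiff(items, names(x))
  if (length(missing_cols)) {
    stop("missing item(s) for domain ", domain, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(x[, items, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing item score in domain ", domain, call. = FALSE)
  if (any(m < 0 | m > 100)) stop("item scores must lie in [0, 100]", call. = FALSE)
  rowMeans(m)
}

#' Total score
#'
#' The total patient experience score: the sum of all 21 item scores
#' rescaled to 0-100, i.e. the mean of the 21 item scores. All items
#' must be present (complete responders only).
#'
#' @inheritParams domain_score
#' @return numeric vector of total scores.
#' @export
total_score <- function(item_scores) {
  rowMeans(.as_score_matrix(item_scores))
}

#' Score the respondents of a trial dataset
#'
#' Rescales the raw item responses of every respondent and computes the
#' six domain scores and the total score.
#'
#' @param data a `trial_data` object (see [generate_trial()],
#'   [read_trial()]) or a patient-level data.frame with columns
#'   `patient_id`, `responded` and raw items `q1`..`q21`.
#' @return data.frame with one row per respondent: `patient_id`,
#'   `total`, the six domain scores, and the 21 rescaled item scores.
#' @export
pxa_scores <- function(data) {
  df <- if (inherits(data, "trial_data")) data$patients else as.data.frame(data)
  resp <- df[df$responded, , drop = FALSE]
  it <- pxa_items()
  sc <- matrix(NA_real_, nrow(resp), 21, dimnames = list(NULL, it$item))
  for (j in it$item) sc[, j] <- rescale_item(j, resp[[j]])
  out <- data.frame(patient_id = resp$patient_id, stringsAsFactors = FALSE)
  out$total <- rowMeans(sc)
  for (d in names(pxa_domains())) out[[d]] <- domain_score(sc, d)
  cbind(out, as.data.frame(sc))
}

#' Extract an outcome vector aligned to the randomized sample
#'
#' Returns the chosen score for every randomized patient, `NA` for
#' nonrespondents, in the row order of the dataset -- the form consumed
#' by the estimation functions.
#'
#' @inheritParams pxa_scores
#' @param outcome `"total"` or one of the six domain names.
#' @param scores optional precomputed result of [pxa_scores()].
#' @return numeric vector with one entry per randomized patient.
#' @export
outcome_vector <- function(data, outcome = "total", scores = NULL) {
  df <- if (inherits(data, "trial_data")) data$patients else as.data.frame(data)
  choices <- c("total", names(pxa_domains()))
  if (!outcome %in% choices) {
    stop("outcome must be one of: ", paste(choices, collapse = ", "), call. = FALSE)
  }
  if (is.null(scores)) scores <- pxa_scores(data)
  y <- rep(NA_real_, nrow(df))
  idx <- match(scores$patient_id, df$patient_id)
  y[idx] <- scores[[outcome]]
  y
}
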