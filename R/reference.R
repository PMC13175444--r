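# Published summaries of the 2022 four-hospital Korean PXA mode
# experiment (3200 randomized inpatients, telephone vs mobile web).
# These are the calibration anchors for the synthetic generator and the
# arithmetic cross-checks in the test suite.

#' Published response-rate counts of the reference mode experiment
#'
#' Respondent and randomized counts by participant characteristic and
#' survey mode from the 2022 Korean PXA mode experiment (1600 patients
#' per arm), together with the response percentages as printed (one
#' decimal place).
#'
#' @return data.frame with columns `characteristic`, `level`, `arm`
#'   (`"all"`, `"telephone"`, `"mobile_web"`), `respondents`,
#'   `randomized`, `printed_pct`.
#' @export
#' @examples
#' x <- reference_response_counts()
#' subset(x, characteristic == "total")
reference_response_counts <- function() {
  rows <- list(
    # characteristic, level, r_all, n_all, p_all, r_tel, n_tel, p_tel, r_mob, n_mob, p_mob
    c("total", "total",          878, 3200, 27.4, 358, 1600, 22.4, 520, 1600, 32.5),
    c("sex", "male",             445, 1583, 28.1, 195,  799, 24.4, 250,  784, 31.9),
    c("sex", "female",           433, 1617, 26.8, 163,  801, 20.3, 270,  816, 33.1),
    c("age_group", "19-39",      115,  414, 27.8,  31,  189, 16.4,  84,  225, 37.3),
    c("age_group", "40-59",      359, 1030, 34.9, 128,  525, 24.4, 231,  505, 45.7),
    c("age_group", "60-69",      253,  878, 28.8, 116,  439, 26.4, 137,  439, 31.2),
    c("age_group", "70+",        151,  878, 17.2,  83,  447, 18.6,  68,  431, 15.8),
    c("care_field", "medical",   310, 1268, 24.4, 123,  612, 20.1, 187,  656, 28.5),
    c("care_field", "surgical_other", 568, 1932, 29.4, 235, 988, 23.8, 333, 944, 35.3),
    c("hospital", "A",           314, 1000, 31.4, 136,  500, 27.2, 178,  500, 35.6),
    c("hospital", "B",           288, 1002, 28.7, 127,  502, 25.3, 161,  500, 32.2),
    c("hospital", "C",           158,  666, 23.7,  50,  334, 15.0, 108,  332, 32.5),
    c("hospital", "D",           118,  532, 22.2,  45,  264, 17.0,  73,  268, 27.2)
  )
  long <- do.call(rbind, lapply(rows, function(r) {
    data.frame(
      characteristic = r[1], level = r[2],
      arm = c("all", "telephone", "mobile_web"),
      respondents = as.numeric(r[c(3, 6, 9)]),
      randomized = as.numeric(r[c(4, 7, 10)]),
      printed_pct = as.numeric(r[c(5, 8, 11)]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(long) <- NULL
  long
}

#' Published respondent score summaries of the reference mode experiment
#'
#' Respondent arm means and SDs on the 0-100 scale for the total score
#' and the six domain scores in the reference experiment, with the
#' printed unadjusted mode differences (mobile web minus telephone) and
#' their 95% confidence limits.
#'
#' @return data.frame with one row per outcome.
#' @export
reference_score_summaries <- function() {
  data.frame(
    outcome = c("total", "nurse", "doctor", "medication_treatment",
                "hospital_environment", "patients_rights", "overall_rating"),
    telephone_mean = c(84.92, 89.40, 82.51, 85.08, 86.13, 80.81, 85.22),
    telephone_sd   = c(14.34, 15.20, 18.79, 16.69, 18.28, 19.83, 16.94),
    mobile_mean    = c(81.51, 86.02, 78.43, 81.98, 79.50, 78.76, 84.12),
    mobile_sd      = c(16.35, 17.06, 19.93, 18.78, 20.85, 18.47, 19.10),
    unadjusted_diff = c(-3.41, -3.38, -4.08, -3.10, -6.63, -2.05, -1.10),
    unadjusted_lo   = c(-5.51, -5.58, -6.71, -5.52, -9.30, -4.61, -3.56),
    unadjusted_hi   = c(-1.31, -1.18, -1.46, -0.68, -3.96,  0.52,  1.36),
    stringsAsFactors = FALSE
  )
}
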