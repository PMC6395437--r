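#' @include phantom.R
NULL

#' Simulate a pre-treatment stroke cohort with known ground truth
#'
#' Draws per-patient ground-truth lesion and CNAWM APTW values from
#' normal distributions and couples the NIHSS severity score to the true
#' lesion APTW through a bivariate-normal linkage with a specified
#' population correlation: `nihss_raw = mu + sigma * (r * z + sqrt(1 -
#' r^2) * e)` where `z` standardizes the lesion APTW, so the generating
#' model attains the target correlation in expectation.  The integer
#' `nihss` column is the raw score rounded and clamped to \[0, 42\];
#' `nihss_raw` keeps the continuous score.  Onset times are resampled
#' from the bundled demographics table unless given.
#'
#' @param n number of patients.
#' @param lesion_mean,lesion_sd ground-truth lesion APTW distribution
#'   (percent).
#' @param cnawm_mean,cnawm_sd ground-truth CNAWM APTW distribution.
#' @param nihss_mean,nihss_sd NIHSS population moments.
#' @param target_r population correlation between lesion APTW and NIHSS
#'   (must lie in \[-1, 1\]).
#' @param onset_times_h optional vector of onset-to-scan times in hours.
#' @param seed integer seed.
#' @return a validated cohort data.frame (see [validateCohortTable()])
#'   with additional column `nihss_raw`.
#' @examples
#' co <- simulateCohort(n = 43, seed = 1)
#' cor(co$lesion_aptw_pct, co$nihss)
#' @export
simulateCohort <- function(n = 43, lesion_mean = -1.01, lesion_sd = 0.91,
                           cnawm_mean = 0.36, cnawm_sd = 0.45,
                           nihss_mean = 6.0, nihss_sd = 3.9,
                           target_r = -0.491, onset_times_h = NULL,
                           seed = 1L) {
  if (!is.finite(target_r) || abs(target_r) > 1)
    stop("target correlation must lie in [-1, 1]")
  stopifnot(n >= 1, lesion_sd >= 0, cnawm_sd >= 0, nihss_sd >= 0)
  withr_seed(as.integer(seed), function() {
    z <- stats::rnorm(n)
    e <- stats::rnorm(n)
    lesion <- lesion_mean + lesion_sd * z
    nihss_raw <- nihss_mean +
      nihss_sd * (target_r * z + sqrt(1 - target_r^2) * e)
    nihss <- pmin(42, pmax(0, round(nihss_raw)))
    cnawm <- cnawm_mean + cnawm_sd * stats::rnorm(n)
    onset <- if (is.null(onset_times_h))
      sample(demographicsTable()$onset_time_h, n, replace = TRUE)
    else rep_len(onset_times_h, n)
    d <- data.frame(
      patient_id = seq_len(n), scan_id = sprintf("P%03d_S1", seq_len(n)),
      phase = "pre", nihss = nihss, onset_time_h = onset,
      post_treatment_time_h = NA_real_, treated = FALSE, effective = NA,
      lesion_aptw_pct = lesion, cnawm_aptw_pct = cnawm,
      contrast_pct = lesion - cnawm, nihss_raw = nihss_raw)
    validateCohortTable(d)
  })
}

#' Bundled demographics of the reference cohort
#'
#' Per-patient NIHSS at arrival and onset-to-first-scan time (hours) for
#' the 43-patient reference stroke cohort, with the follow-up scan
#' schedule (days since symptom onset) of the 26 patients who were
#' rescanned after treatment.
#'
#' @return [demographicsTable()]: data.frame with columns `patient_id`,
#'   `nihss`, `onset_time_h`; [followUpTable()]: data.frame with columns
#'   `patient_id`, `followup_day`.
#' @export
demographicsTable <- function() {
  utils::read.csv(system.file("extdata", "cohort_demographics.csv",
                              package = "aptwcest"))
}

#' @rdname demographicsTable
#' @export
followUpTable <- function() {
  utils::read.csv(system.file("extdata", "cohort_followup.csv",
                              package = "aptwcest"))
}

#' Assemble a scan-level cohort table from demographics
#'
#' One pre-treatment row per patient (at the recorded onset-to-scan
#' time) plus one post-treatment row per follow-up scan.  For follow-up
#' scans the onset time is the follow-up day converted to hours and the
#' post-treatment time is the interval from the first (pre-treatment)
#' scan, when treatment began.  Measurement columns are `NA` unless
#' filled in by a simulation or measurement stage.
#'
#' @param demographics data.frame as from [demographicsTable()].
#' @param followup data.frame as from [followUpTable()] (or `NULL` for a
#'   pre-treatment-only cohort).
#' @param ineffective_ids patient ids whose treatment response was
#'   ineffective (their post rows get `effective = FALSE`).
#' @return a validated cohort data.frame.
#' @export
cohortFromDemographics <- function(demographics = demographicsTable(),
                                   followup = followUpTable(),
                                   ineffective_ids = integer()) {
  pre <- data.frame(
    patient_id = demographics$patient_id,
    scan_id = sprintf("P%03d_S1", demographics$patient_id),
    phase = "pre", nihss = demographics$nihss,
    onset_time_h = demographics$onset_time_h,
    post_treatment_time_h = NA_real_, treated = FALSE, effective = NA,
    lesion_aptw_pct = NA_real_, cnawm_aptw_pct = NA_real_,
    contrast_pct = NA_real_)
  rows <- pre
  if (!is.null(followup) && nrow(followup)) {
    onset_h <- setNames(demographics$onset_time_h,
                        demographics$patient_id)
    post <- data.frame(
      patient_id = followup$patient_id,
      scan_id = sprintf("P%03d_F%d", followup$patient_id,
                        stats::ave(followup$patient_id,
                                   followup$patient_id, FUN = seq_along)),
      phase = "post", nihss = NA_integer_,
      onset_time_h = followup$followup_day * 24,
      post_treatment_time_h = followup$followup_day * 24 -
        onset_h[as.character(followup$patient_id)],
      treated = TRUE,
      effective = !(followup$patient_id %in% ineffective_ids),
      lesion_aptw_pct = NA_real_, cnawm_aptw_pct = NA_real_,
      contrast_pct = NA_real_)
    rows <- rbind(pre, post)
  }
  rownames(rows) <- NULL
  validateCohortTable(rows)
  rows
}
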