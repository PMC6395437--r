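#' @include AllClasses.R
NULL

#' Published group summaries of the reference cohort
#'
#' The reported group means and SDs (percent of bulk water signal for
#' APTW measures) of the reference stroke cohort: per post-treatment
#' time bin (`by_post_treatment`) and per onset-time bin split into pre-
#' and post-treatment groups (`by_onset`).  Used as simulation inputs
#' (e.g. the pre-treatment lesion row parameterizes [simulateCohort()])
#' and for internal-consistency checks such as the APTW-contrast
#' identity `contrast = lesion - CNAWM`.
#'
#' @return list of two data.frames, `by_post_treatment` and `by_onset`.
#' @export
referenceGroupTables <- function() {
  list(
    by_post_treatment = utils::read.csv(
      system.file("extdata", "reference_groups_post_treatment.csv",
                  package = "aptwcest")),
    by_onset = utils::read.csv(
      system.file("extdata", "reference_groups_onset.csv",
                  package = "aptwcest")))
}
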