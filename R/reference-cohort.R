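#' Reference Parkinson's disease cohort
#'
#' Clinical characteristics of a published 23-patient resting-state MEG
#' cohort (sex, age, more-affected side, MDS-UPDRS-III akinesia score sum,
#' medication state during recording, levodopa-equivalent daily dose, disease
#' duration). Ships as a packaged CSV and serves both as a realistic template
#' for [simulate_cohort()] covariates and as a fixed input for summary
#' statistics (n = 23, 11 men, mean age 65.3 +/- 7.9 years).
#'
#' @return A tibble with 23 rows and columns `id`, `sex`, `age_years`,
#'   `affected_side`, `akinesia_score`, `state`, `ledd_mg`,
#'   `duration_years`, `group` (all `"patient"`).
#' @examples
#' pd_reference_cohort()
#' @export
pd_reference_cohort <- function() {
  path <- system.file("extdata", "pd_reference_cohort.csv", package = "megpac",
                      mustWork = TRUE)
  read_cohort(path)
}
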