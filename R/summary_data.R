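#' Bundled cohort summary tables
#'
#' Per-group demographic and clinical summary statistics of a published
#' four-group childhood-maltreatment by depression cohort (depressed
#' patients and healthy controls, each split by maltreatment exposure;
#' group sizes 84/46/32/90). `cohort_summary()` returns the continuous
#' variables (age, education, symptom scales, CTQ total and subscales) as a
#' tidy long table of per-group mean, SD and n; `cohort_sex_counts()`
#' returns the female/male counts per group. These tables drive two things:
#' the worked reconstruction of the cohort's test statistics via
#' [reconstruct_summary_statistics()], and the default covariate and score
#' distributions of the synthetic cohort generator.
#'
#' @returns A tibble; see Description.
#' @export
cohort_summary <- function() {
  path <- system.file("extdata", "cohort_summary_continuous.csv", package = "richclubr")
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname cohort_summary
#' @export
cohort_sex_counts <- function() {
  path <- system.file("extdata", "cohort_sex_counts.csv", package = "richclubr")
  readr::read_csv(path, show_col_types = FALSE)
}
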