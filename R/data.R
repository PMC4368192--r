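#' Reference SQRFM evaluation results for 27 tablet batches
#'
#' Published evaluation parameters for 27 production batches (S1-S27) of
#' Compound Bismuth Aluminate tablets, whose licorice-derived herbal fraction
#' was fingerprinted by HPLC-DAD at five detection wavelengths. For every
#' sample the table holds the ratio similarity `sf_prime`, the corrected
#' quantified ratio similarity `mf` (percent), the dissimilarity coefficient
#' `alpha` and the reported quality `grade`, per wavelength channel
#' (`"250"`, `"276"`, `"330"`, `"360"`, `"375"` nm) and for the
#' entropy-integrated channel (`"integrated"`). Values are as printed in the
#' source report (2-3 significant decimals); three per-wavelength grade
#' cells sit exactly on threshold boundaries and differ by one grade from
#' what the printed parameters imply (see the package vignette).
#'
#' @return A tibble with columns `sample_id`, `channel`, `sf_prime`, `mf`,
#'   `alpha`, `grade`.
#' @seealso [cbat_p5c()], [cbat_ec50()], [sqrfm_grade()]
#' @export
cbat_evaluation <- function() {
  readr::read_csv(
    system.file("extdata", "cbat_sqrfm_evaluation.csv", package = "sqrfm"),
    show_col_types = FALSE,
    col_types = readr::cols(sample_id = readr::col_character(),
                            channel = readr::col_character(),
                            .default = readr::col_double()))
}

#' Reference P5C marker-content indices for 27 tablet batches
#'
#' The geometric-mean marker-content index P5C (five licorice markers:
#' glycyrrhizic acid, liquiritin, isoliquiritin, isoliquiritigenin and
#' isoliquiritin apioside) for the same 27 batches as [cbat_evaluation()],
#' on the fraction scale as printed (~1.0 corresponds to 100 percent).
#'
#' @return A tibble with columns `sample_id`, `p5c`.
#' @export
cbat_p5c <- function() {
  readr::read_csv(
    system.file("extdata", "cbat_p5c.csv", package = "sqrfm"),
    show_col_types = FALSE,
    col_types = readr::cols(sample_id = readr::col_character(),
                            p5c = readr::col_double()))
}

#' Reference antioxidant activities and model predictions for 27 batches
#'
#' Measured hydroxyl-radical scavenging EC50 values (mg/ml, mean of three
#' determinations with standard deviation) for the 27 batches of
#' [cbat_evaluation()], together with the reported spectrum-effect PLSR
#' results: the leave-one-out cross-validation relative error `re_cv`
#' (percent), the final-model `ec50_predicted` (mg/ml) and its relative
#' error `re_predicted` (percent). Samples S17 and S25 are the two singular
#' points (|`re_cv`| > 20 percent).
#'
#' @return A tibble with columns `sample_id`, `ec50_measured`, `ec50_sd`,
#'   `re_cv`, `ec50_predicted`, `re_predicted`.
#' @export
cbat_ec50 <- function() {
  readr::read_csv(
    system.file("extdata", "cbat_ec50.csv", package = "sqrfm"),
    show_col_types = FALSE,
    col_types = readr::cols(sample_id = readr::col_character(),
                            .default = readr::col_double()))
}
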