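#' Hydroxyl-radical scavenging ratio
#'
#' Fenton / crystal-violet assay arithmetic: hydroxyl radicals fade the dye,
#' and an antioxidant that scavenges them preserves absorbance. The
#' scavenging ratio is
#' \eqn{SR = 100 (A_S - A_B) / (A_0 - A_b)} percent, where \eqn{A_S} and
#' \eqn{A_B} are the absorbances of the positive (sample) and negative
#' (solvent) controls and \eqn{A_0}, \eqn{A_b} those of the blank without and
#' with peroxide. Swapping `a_s` and `a_b_ctrl` flips the sign.
#'
#' @param a_s Positive-control absorbance(s).
#' @param a_b_ctrl Negative-control absorbance(s).
#' @param a0 Blank absorbance without hydrogen peroxide.
#' @param ab Blank absorbance with hydrogen peroxide (fading makes
#'   `ab < a0`).
#' @return Scavenging ratio(s) in percent.
#' @examples
#' scavenging_ratio(0.60, 0.40, 0.90, 0.50)  # 50
#' @export
scavenging_ratio <- function(a_s, a_b_ctrl, a0, ab) {
  if (any(a0 == ab)) abort("a0 and ab must differ (division by zero)")
  100 * (a_s - a_b_ctrl) / (a0 - ab)
}

#' EC50 from a scavenging-ratio dose series
#'
#' The effective concentration scavenging 50\% of the radicals, computed from
#' (concentration, SR) pairs either by inverse prediction on an OLS line of
#' SR on concentration fitted to all levels (`"linear_fit"`, the default) or
#' by linear interpolation between the two levels straddling 50\%
#' (`"bracketing"`). The two agree exactly when SR is exactly linear in
#' concentration. `linear_fit` warns, and `bracketing` errors, when 50\% lies
#' outside the tested range.
#'
#' @param conc Concentrations (mg/ml), >= 2 levels.
#' @param sr Scavenging ratios (percent), same length, not constant.
#' @param method `"linear_fit"` or `"bracketing"`.
#' @return A one-row tibble: `ec50` (mg/ml), `method`, `slope`, `intercept`
#'   (slope/intercept are `NA` for bracketing).
#' @examples
#' ec50_estimate(c(0.4, 0.6), c(40, 60), method = "bracketing")  # 0.5
#' @export
ec50_estimate <- function(conc, sr, method = c("linear_fit", "bracketing")) {
  method <- match.arg(method)
  if (length(conc) != length(sr) || length(conc) < 2) {
    abort("need >= 2 (conc, sr) levels")
  }
  if (sd(sr) == 0) abort("sr must not be constant")
  ord <- order(conc)
  conc <- conc[ord]; sr <- sr[ord]
  if (method == "linear_fit") {
    fit <- lm(sr ~ conc)
    k <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
    if (k == 0) abort("fitted slope is zero; EC50 undefined")
    ec <- (50 - b) / k
    if (ec < min(conc) || ec > max(conc)) {
      warn("EC50 lies outside the tested concentration range (extrapolated)")
    }
    return(tibble(ec50 = ec, method = method, slope = k, intercept = b))
  }
  below <- which(sr <= 50)
  above <- which(sr >= 50)
  if (length(below) == 0 || length(above) == 0) {
    abort("no pair of levels straddles SR = 50%; cannot bracket",
          class = "sqrfm_extrapolation_error")
  }
  i <- max(below); j <- min(above)
  if (sr[i] == 50) {
    ec <- conc[i]
  } else {
    ec <- conc[i] + (50 - sr[i]) * (conc[j] - conc[i]) / (sr[j] - sr[i])
  }
  tibble(ec50 = ec, method = method, slope = NA_real_, intercept = NA_real_)
}

#' EC50 for a batch of assay records
#'
#' Computes per-level scavenging ratios from raw absorbances and an EC50 per
#' sample. Expects one row per sample x concentration level.
#'
#' @param assay A data frame with columns `sample_id`, `conc_mg_ml`, `a_b`
#'   (negative control) and `a_s` (positive control).
#' @param a0,ab Blank absorbances without / with hydrogen peroxide (scalars
#'   for the whole assay).
#' @param method Passed to [ec50_estimate()].
#' @return A tibble with one row per sample: `ec50`, `n_levels`; the
#'   per-level SR table is attached as attribute `"sr"`.
#' @export
ec50_batch <- function(assay, a0, ab, method = c("linear_fit", "bracketing")) {
  method <- match.arg(method)
  assay <- as_tibble(assay)
  need <- c("sample_id", "conc_mg_ml", "a_b", "a_s")
  if (!all(need %in% names(assay))) {
    abort("assay needs columns sample_id, conc_mg_ml, a_b, a_s")
  }
  assay$sr <- scavenging_ratio(assay$a_s, assay$a_b, a0, ab)
  out <- assay |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(g, key) {
      est <- ec50_estimate(g$conc_mg_ml, g$sr, method = method)
      tibble(ec50 = est$ec50, n_levels = nrow(g))
    }) |>
    dplyr::ungroup()
  attr(out, "sr") <- assay
  out
}
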