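#' Fit marker calibration lines
#'
#' Ordinary least squares of peak area on injected mass, per compound, as
#' used to calibrate marker-compound quantification. Detection and
#' quantification limits follow the signal-to-noise convention
#' `LOD = 3 sigma / k` and `LOQ = 10 sigma / k`, given a user-supplied
#' baseline-noise estimate (the package does not estimate noise from raw
#' chromatograms), so `LOQ / LOD = 10/3` by construction.
#'
#' @param standards A data frame with columns `mass_ug` and `area`, and
#'   optionally `compound` (one calibration line is fitted per compound).
#' @param noise_sd Baseline noise standard deviation in area units (scalar or
#'   named per compound); `NA` limits are reported when omitted.
#' @return A tibble of class `calibration` with columns `compound`, `slope`,
#'   `intercept`, `r`, `mass_min`, `mass_max`, `lod_ug`, `loq_ug`, `n`. The
#'   underlying `lm` fits are attached as attribute `"fits"`.
#' @examples
#' std <- data.frame(mass_ug = c(1, 2, 4), area = c(3, 5, 9))
#' fit_calibration(std)  # exact line y = 2x + 1
#' @export
fit_calibration <- function(standards, noise_sd = NULL) {
  standards <- as_tibble(standards)
  if (!all(c("mass_ug", "area") %in% names(standards))) {
    abort("standards need columns mass_ug and area")
  }
  if (!("compound" %in% names(standards))) standards$compound <- "marker"
  groups <- split(standards, standards$compound)
  fits <- purrr::map(groups, function(g) {
    if (nrow(g) < 3 || dplyr::n_distinct(g$mass_ug) < 3) {
      abort("need >= 3 distinct calibration levels per compound")
    }
    lm(area ~ mass_ug, data = g)
  })
  noise_of <- function(cmp) {
    if (is.null(noise_sd)) return(NA_real_)
    if (!is.null(names(noise_sd))) return(unname(noise_sd[cmp]))
    noise_sd
  }
  out <- purrr::imap(groups, function(g, cmp) {
    fit <- fits[[cmp]]
    k <- unname(coef(fit)[2])
    ns <- noise_of(cmp)
    tibble(compound = cmp,
           slope = k,
           intercept = unname(coef(fit)[1]),
           r = cor(g$mass_ug, g$area),
           mass_min = min(g$mass_ug), mass_max = max(g$mass_ug),
           lod_ug = 3 * ns / k, loq_ug = 10 * ns / k,
           n = nrow(g))
  }) |> dplyr::bind_rows()
  attr(out, "fits") <- fits
  class(out) <- c("calibration", class(out))
  out
}

#' @export
tidy.calibration <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(attr(x, "fits"), function(fit, cmp) {
    s <- summary(fit)$coefficients
    tibble(compound = cmp,
           term = c("intercept", "slope"),
           estimate = s[, 1], std.error = s[, 2])
  }))
}

#' @export
glance.calibration <- function(x, ...) {
  dplyr::select(as_tibble(x), dplyr::all_of(
    c("compound", "r", "mass_min", "mass_max", "lod_ug", "loq_ug", "n")))
}

#' Quantify marker contents from peak areas
#'
#' Inverse prediction on the calibration line: the injected marker mass is
#' `(area - intercept) / slope` micrograms, converted to a content in mg/g of
#' sample by the dilution factor and the weighed-in sample mass. `dilution`
#' is the ratio of total extract mass to injected mass divided by 1000 (so
#' that micrograms injected become milligrams in the sample); it depends on
#' the extraction volume and injection volume of the assay and is supplied by
#' the caller.
#'
#' @param samples A data frame with columns `sample_id`, `area`,
#'   `sample_mass_g`, and `compound` when the calibration covers several
#'   compounds.
#' @param calibration A [fit_calibration()] result.
#' @param dilution Unitless dilution/conversion factor (default 1).
#' @return `samples` with added columns `mass_ug` (injected), `content_mg_g`
#'   and `below_loq` (flag; `NA` when the calibration has no noise estimate).
#' @export
quantify_content <- function(samples, calibration, dilution = 1) {
  samples <- as_tibble(samples)
  if (!all(c("sample_id", "area", "sample_mass_g") %in% names(samples))) {
    abort("samples need columns sample_id, area, sample_mass_g")
  }
  if (!("compound" %in% names(samples))) {
    samples$compound <- calibration$compound[1]
  }
  cal <- dplyr::select(as_tibble(calibration), dplyr::all_of(
    c("compound", "slope", "intercept", "loq_ug")))
  out <- samples |>
    dplyr::inner_join(cal, by = "compound") |>
    dplyr::mutate(
      mass_ug = (.data$area - .data$intercept) / .data$slope,
      content_mg_g = .data$mass_ug * dilution / .data$sample_mass_g,
      below_loq = .data$mass_ug < .data$loq_ug) |>
    dplyr::select(-dplyr::all_of(c("slope", "intercept", "loq_ug")))
  if (nrow(out) < nrow(samples)) {
    abort("some samples reference a compound absent from the calibration")
  }
  if (any(out$below_loq %in% TRUE)) {
    warn(paste0(sum(out$below_loq %in% TRUE),
                " area(s) fall below the limit of quantification"))
  }
  out
}

#' Spike-recovery percentage
#'
#' Standard-addition accuracy check: `100 * (found - original) / added`.
#'
#' @param found Total amount measured after spiking.
#' @param original Amount measured before spiking.
#' @param added Amount spiked in (same units).
#' @return Recovery in percent.
#' @examples
#' recovery_pct(1.98, 1.0, 1.0)  # 98
#' @export
recovery_pct <- function(found, original, added) {
  if (any(added <= 0)) abort("added amount must be > 0")
  100 * (found - original) / added
}

#' Marker content percentages and the P5C index
#'
#' `marker_percentages()` expresses a sample's marker contents relative to
#' the batch mean content of each marker,
#' \eqn{P_i = 100 \cdot (z_i / \bar z_i) \cdot f}, with `f` the mass
#' coefficient of the sample. `p5c()` is their geometric
#' ("logarithm-exponent") mean \eqn{P_{5C} = \exp(\frac{1}{m}\sum \ln P_i)},
#' the single-number content index; by the AM-GM inequality it never exceeds
#' the arithmetic mean of the \eqn{P_i} and equals it only when all
#' \eqn{P_i} agree.
#'
#' @param z Positive vector of a sample's marker contents (mg/g).
#' @param z_bar Positive vector of batch mean contents, same order.
#' @param f Mass coefficient of the sample (positive scalar).
#' @param p Positive vector of percentages `P_i`.
#' @return `marker_percentages()`: the vector of `P_i` (percent);
#'   `p5c()`: the scalar index (percent).
#' @examples
#' p5c(c(50, 200, 100, 100, 100))  # exactly 100
#' @export
marker_percentages <- function(z, z_bar, f = 1) {
  if (any(z <= 0) || any(z_bar <= 0)) abort("contents must be > 0")
  if (length(z) != length(z_bar)) abort("z and z_bar lengths differ")
  if (f <= 0) abort("f must be > 0")
  100 * (z / z_bar) * f
}

#' @rdname marker_percentages
#' @export
p5c <- function(p) {
  if (any(p <= 0)) abort("percentages must be > 0")
  exp(mean(log(p)))
}

#' Per-sample P5C indices for a batch
#'
#' Computes batch mean contents per marker, each sample's \eqn{P_i}
#' percentages (mass-corrected via `f`) and the geometric-mean P5C index.
#'
#' @param contents A data frame with columns `sample_id`, `compound`,
#'   `content_mg_g`, and optionally `f` (per-sample mass coefficient,
#'   default 1).
#' @return A tibble with one row per sample: `p5c` (percent), with the long
#'   `P_i` table attached as attribute `"percentages"`.
#' @export
p5c_index <- function(contents) {
  contents <- as_tibble(contents)
  need <- c("sample_id", "compound", "content_mg_g")
  if (!all(need %in% names(contents))) {
    abort("contents need columns sample_id, compound, content_mg_g")
  }
  if (!("f" %in% names(contents))) contents$f <- 1
  if (any(contents$content_mg_g <= 0)) abort("contents must be > 0")
  long <- contents |>
    dplyr::group_by(.data$compound) |>
    dplyr::mutate(z_bar = mean(.data$content_mg_g)) |>
    dplyr::ungroup() |>
    dplyr::mutate(p = marker_percentages(.data$content_mg_g, .data$z_bar) *
                    .data$f)
  out <- long |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(p5c = p5c(.data$p), .groups = "drop")
  attr(out, "percentages") <- dplyr::select(long, dplyr::all_of(
    c("sample_id", "compound", "content_mg_g", "z_bar", "f", "p")))
  out
}

#' Correlate the P5C content index with the quantified ratio similarity
#'
#' Pearson correlation and OLS line of the per-sample P5C index on the MF
#' values, the check that quantified fingerprinting tracks multi-component
#' quantification. P5C values are accepted on either the percent (~100) or
#' fraction (~1) scale and normalised to percent; Pearson's r is unaffected
#' by the choice.
#'
#' @param p5c Numeric vector of per-sample P5C values.
#' @param mf Numeric vector of per-sample MF values (percent), same order.
#' @return A one-row tibble: `r`, `slope`, `intercept`, `n`.
#' @export
correlate_p5c_mf <- function(p5c, mf) {
  if (length(p5c) != length(mf) || length(p5c) < 3) {
    abort("need equal-length vectors with >= 3 samples")
  }
  if (stats::median(p5c) < 5) p5c <- 100 * p5c
  if (sd(p5c) == 0 || sd(mf) == 0) abort("zero variance in p5c or mf")
  fit <- lm(p5c ~ mf)
  tibble(r = cor(mf, p5c),
         slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         n = length(p5c))
}
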