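#' SQRFM similarity statistics
#'
#' The quantified ratio fingerprint statistics for a sample fingerprint
#' vector `x` against a reference vector `y`:
#'
#' * `sqrfm_sf()` — the conventional cosine "Similarity",
#'   \eqn{S_F = \sum x_i y_i / (\sqrt{\sum x_i^2}\sqrt{\sum y_i^2})}.
#' * `sqrfm_sf_prime()` — the ratio similarity \eqn{S_F'}: with
#'   \eqn{r_i = x_i/y_i}, \eqn{S_F' = \sum r_i / \sqrt{n \sum r_i^2}}, i.e.
#'   the cosine between the ratio vector and the all-ones vector. Large and
#'   small peaks carry equal weight, so major peaks cannot mask minor ones.
#' * `sqrfm_sm()` — the mean of \eqn{S_F} and \eqn{S_F'}.
#' * `sqrfm_m()` — the mean total content
#'   \eqn{M = 100 \cdot \frac{1}{n}\sum r_i} (percent).
#' * `sqrfm_mf()` — the corrected quantified ratio similarity
#'   \eqn{M_F = M \cdot S_F' \cdot f} (percent), where `f` is the mass
#'   coefficient \eqn{m_R / m_i} correcting for the weighed-in sample mass.
#' * `sqrfm_alpha()` — the dissimilarity coefficient
#'   \eqn{\alpha = |1 - S_F'|}.
#'
#' For non-negative `x` and positive `y`, \eqn{S_F'} lies in (0, 1] and
#' equals 1 exactly when `x` is proportional to `y` (constant ratios).
#'
#' @param x Sample peak-area vector (non-negative, not all zero), or a
#'   [fingerprint_pair()] in which case `y` and `f` are taken from it.
#' @param y Reference peak-area vector (strictly positive).
#' @param f Mass coefficient (positive scalar).
#' @param sf_prime A ratio-similarity value for `sqrfm_alpha()`.
#' @return A numeric scalar.
#' @examples
#' sqrfm_sf(c(2, 2), c(1, 4))        # 0.8575
#' sqrfm_sf_prime(c(2, 2), c(1, 4))  # also 0.8575 for this pair
#' sqrfm_mf(c(2, 2), c(1, 4), f = 1) # 107.19
#' @name sqrfm_statistics
NULL

unpack_pair <- function(x, y, f) {
  if (inherits(x, "fingerprint_pair")) list(x = x$x, y = x$y, f = x$f)
  else list(x = as.numeric(x), y = as.numeric(y), f = f)
}

#' @rdname sqrfm_statistics
#' @export
sqrfm_sf <- function(x, y = NULL) {
  p <- unpack_pair(x, y, 1)
  if (all(p$x == 0) || all(p$y == 0)) abort("zero-norm fingerprint vector")
  sum(p$x * p$y) / (sqrt(sum(p$x^2)) * sqrt(sum(p$y^2)))
}

#' @rdname sqrfm_statistics
#' @export
sqrfm_sf_prime <- function(x, y = NULL) {
  p <- unpack_pair(x, y, 1)
  check_ratio_args(p)
  r <- p$x / p$y
  sum(r) / sqrt(length(r) * sum(r^2))
}

#' @rdname sqrfm_statistics
#' @export
sqrfm_sm <- function(x, y = NULL) {
  (sqrfm_sf(x, y) + sqrfm_sf_prime(x, y)) / 2
}

#' @rdname sqrfm_statistics
#' @export
sqrfm_m <- function(x, y = NULL) {
  p <- unpack_pair(x, y, 1)
  check_ratio_args(p)
  100 * mean(p$x / p$y)
}

#' @rdname sqrfm_statistics
#' @export
sqrfm_mf <- function(x, y = NULL, f = 1) {
  p <- unpack_pair(x, y, f)
  sqrfm_m(p$x, p$y) * sqrfm_sf_prime(p$x, p$y) * p$f
}

#' @rdname sqrfm_statistics
#' @export
sqrfm_alpha <- function(sf_prime) {
  abs(1 - sf_prime)
}

check_ratio_args <- function(p) {
  if (any(p$y <= 0)) abort("all reference areas y must be > 0")
  if (any(p$x < 0)) abort("sample areas x must be >= 0")
  if (all(p$x == 0)) abort("sample areas x must not all be zero")
  invisible(p)
}

#' The eight-grade SQRFM quality classification table
#'
#' Thresholds of the quality pyramid: grades 1-7 require `SF' >=` the listed
#' minimum, `MF` (percent) inside the listed closed interval and `alpha <=`
#' the listed maximum; anything failing all seven bands falls into grade 8,
#' the warning-gate / adulterant region (`SF' < 0.5`, `alpha > 0.50`, or `MF`
#' outside 50-150). Boundaries are inclusive. Grades 1-5 are considered
#' qualified.
#'
#' @return A tibble with columns `grade`, `sf_prime_min`, `mf_min`, `mf_max`,
#'   `alpha_max` (grade 8 encoded with `NA` / infinite bounds).
#' @export
sqrfm_grade_table <- function() {
  tibble(
    grade = 1:8,
    sf_prime_min = c(0.95, 0.90, 0.85, 0.80, 0.70, 0.60, 0.50, NA),
    mf_min = c(95, 90, 80, 75, 70, 60, 50, 0),
    mf_max = c(105, 110, 120, 125, 130, 140, 150, Inf),
    alpha_max = c(0.05, 0.10, 0.15, 0.20, 0.30, 0.40, 0.50, NA)
  )
}

#' Assign SQRFM quality grades
#'
#' Each parameter is graded as the smallest grade (1-7) whose threshold it
#' meets (`SF' >=` minimum, `MF` within the closed band, `alpha <=` maximum),
#' or 8 if it meets none; the overall grade is the worst of the three
#' per-parameter grades. Worsening any single parameter can therefore never
#' improve the overall grade.
#'
#' @param sf_prime,mf,alpha Numeric vectors (recycled to common length) of
#'   the three SQRFM parameters; `mf` in percent.
#' @param grade_table Threshold table, by default [sqrfm_grade_table()].
#' @return An integer vector of grades in 1..8.
#' @examples
#' sqrfm_grade(0.95, 84.0, 0.05)   # 3
#' sqrfm_grade(0.97, 185.1, 0.03)  # 8 (MF outside 50-150)
#' @export
sqrfm_grade <- function(sf_prime, mf, alpha, grade_table = sqrfm_grade_table()) {
  n <- max(length(sf_prime), length(mf), length(alpha))
  sf_prime <- rep_len(sf_prime, n)
  mf <- rep_len(mf, n)
  alpha <- rep_len(alpha, n)
  if (anyNA(sf_prime) || anyNA(mf) || anyNA(alpha)) {
    abort("grade parameters must be finite")
  }
  if (any(mf < 0)) abort("mf must be >= 0")
  gt <- grade_table[grade_table$grade <= 7, ]
  first_grade <- function(ok) {
    # ok: n x 7 logical; smallest satisfying grade, else 8
    idx <- apply(ok, 1, function(z) match(TRUE, z))
    ifelse(is.na(idx), 8L, as.integer(idx))
  }
  g_sfp <- first_grade(outer(sf_prime, gt$sf_prime_min, `>=`))
  g_mf <- first_grade(outer(mf, gt$mf_min, `>=`) & outer(mf, gt$mf_max, `<=`))
  g_alpha <- first_grade(outer(alpha, gt$alpha_max, `<=`))
  pmax(g_sfp, g_mf, g_alpha)
}

#' Evaluate one sample fingerprint against the reference
#'
#' Computes the full SQRFM statistic set (\eqn{S_F}, \eqn{S_F'}, \eqn{S_m},
#' \eqn{M}, \eqn{M_F}, \eqn{\alpha}) and the quality grade for one
#' sample/reference pair.
#'
#' @param pair A [fingerprint_pair()].
#' @param grade_table Threshold table, by default [sqrfm_grade_table()].
#' @return A one-row tibble with columns `sample_id`, `wavelength_nm`, `n`,
#'   `f`, `sf`, `sf_prime`, `sm`, `m`, `mf`, `alpha`, `grade`.
#' @export
sqrfm_evaluate <- function(pair, grade_table = sqrfm_grade_table()) {
  stopifnot(inherits(pair, "fingerprint_pair"))
  sfp <- sqrfm_sf_prime(pair)
  res <- tibble(
    sample_id = pair$sample_id,
    wavelength_nm = pair$wavelength_nm,
    n = pair$n,
    f = pair$f,
    sf = sqrfm_sf(pair),
    sf_prime = sfp,
    sm = NA_real_,
    m = sqrfm_m(pair),
    mf = NA_real_,
    alpha = sqrfm_alpha(sfp)
  )
  res$sm <- (res$sf + res$sf_prime) / 2
  res$mf <- res$m * res$sf_prime * res$f
  res$grade <- sqrfm_grade(res$sf_prime, res$mf, res$alpha, grade_table)
  res
}

#' Evaluate a whole batch of fingerprints
#'
#' The main entry point for batch quality monitoring: takes an aligned peak
#' table, builds (or accepts) the reference fingerprint profile, and returns
#' the SQRFM statistics and grade for every sample at every wavelength.
#'
#' @param peaks Aligned peak table (see [align_peaks()]).
#' @param rfp Reference profile from [build_rfp()]; computed from `peaks`
#'   when `NULL`.
#' @param grade_table Threshold table, by default [sqrfm_grade_table()].
#' @return A tibble of class `sqrfm_eval`, one row per sample x wavelength,
#'   with the RFP attached as attribute `"rfp"`.
#' @examples
#' sim <- simulate_batch(sim_config(n_samples = 5, n_peaks = 8,
#'                                  wavelengths = 250), seed = 1)
#' evaluate_fingerprints(sim$peaks)
#' @export
evaluate_fingerprints <- function(peaks, rfp = NULL,
                                  grade_table = sqrfm_grade_table()) {
  peaks <- validate_peak_table(peaks)
  rfp <- rfp %||% build_rfp(peaks)
  out <- fingerprint_pairs(peaks, rfp) |>
    purrr::map(sqrfm_evaluate, grade_table = grade_table) |>
    dplyr::bind_rows()
  attr(out, "rfp") <- rfp
  class(out) <- c("sqrfm_eval", class(out))
  out
}

#' Plot SQRFM batch evaluation results
#'
#' Tile map of quality grades by sample and wavelength, the at-a-glance
#' summary of batch consistency.
#'
#' @param object A `sqrfm_eval` (or integrated) result tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sqrfm_eval <- function(object, ...) {
  df <- as_tibble(object)
  df$wavelength <- factor(df$wavelength_nm)
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$wavelength,
                                   fill = factor(.data$grade, levels = 1:8))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(
      values = grDevices::hcl.colors(8, "RdYlGn", rev = TRUE),
      drop = FALSE, name = "grade") +
    ggplot2::labs(x = "sample", y = "wavelength (nm)") +
    ggplot2::theme_minimal()
}
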