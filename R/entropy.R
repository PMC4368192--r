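#' Shannon entropy of a fingerprint profile
#'
#' The information entropy of a peak profile, used to weight detection
#' wavelengths when fusing multi-wavelength evaluations: profiles spreading
#' signal over many peaks carry more fingerprint information and receive
#' larger weight. Values are normalised to a discrete distribution
#' \eqn{p_i = v_i / \sum v} and the entropy is
#' \eqn{S = -\sum p_i \ln p_i} (nats); zero-valued peaks contribute nothing.
#'
#' @param profile Numeric vector of non-negative peak values with a positive
#'   sum (areas, or ratio-fingerprint values).
#' @return Entropy in nats; `ln(n)` for a uniform n-peak profile, 0 for a
#'   single nonzero peak.
#' @examples
#' fingerprint_entropy(rep(1, 8))           # log(8)
#' fingerprint_entropy(c(0.5, 0.25, 0.25))  # 1.0397
#' @export
fingerprint_entropy <- function(profile) {
  profile <- as.numeric(profile)
  if (anyNA(profile) || any(profile < 0)) {
    abort("profile values must be non-negative and complete")
  }
  s <- sum(profile)
  if (s <= 0) abort("profile must have a positive sum")
  p <- profile / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-wavelength entropies of a batch's ratio fingerprints
#'
#' Computes, at each wavelength, the Shannon entropy of every sample's ratio
#' fingerprint (the profile of `x_i / y_i` against the reference), and
#' summarises one entropy `S_j` per wavelength as the mean over samples
#' (set `per_sample = TRUE` to keep the sample-level values).
#'
#' @param peaks Aligned peak table of the batch.
#' @param rfp Reference profile; computed from `peaks` when `NULL`.
#' @param per_sample Return one row per sample x wavelength instead of the
#'   per-wavelength mean.
#' @return A tibble with columns `wavelength_nm` and `entropy` (plus
#'   `sample_id` when `per_sample = TRUE`).
#' @export
channel_entropies <- function(peaks, rfp = NULL, per_sample = FALSE) {
  peaks <- validate_peak_table(peaks)
  rfp <- rfp %||% build_rfp(peaks)
  pairs <- fingerprint_pairs(peaks, rfp)
  per <- purrr::map(pairs, function(p) {
    tibble(sample_id = p$sample_id, wavelength_nm = p$wavelength_nm,
           entropy = fingerprint_entropy(p$x / p$y))
  }) |> dplyr::bind_rows()
  if (per_sample) return(per)
  per |>
    dplyr::group_by(.data$wavelength_nm) |>
    dplyr::summarise(entropy = mean(.data$entropy), .groups = "drop")
}

#' Entropy weights across wavelengths
#'
#' Normalises per-wavelength entropies to weights
#' \eqn{e_j = S_j / \sum_j S_j}, which sum to one.
#'
#' @param entropies Positive numeric vector of per-wavelength entropies.
#' @return Numeric vector of weights.
#' @export
entropy_weights <- function(entropies) {
  entropies <- as.numeric(entropies)
  if (anyNA(entropies) || any(entropies <= 0)) {
    abort("entropies must be positive")
  }
  entropies / sum(entropies)
}

#' Integrate per-wavelength SQRFM results with entropy weights
#'
#' Fuses the per-wavelength parameters into single integrated statistics per
#' sample as entropy-weighted sums:
#' \eqn{S_F'^{int} = \sum_j e_j S_{F,j}'},
#' \eqn{M_F' = \sum_j e_j M_{F,j}} and
#' \eqn{\alpha' = \sum_j e_j \alpha_j} (note that \eqn{\alpha'} is integrated
#' directly, not recomputed as \eqn{|1 - S_F'^{int}|}), then grades the
#' integrated triplet with the usual classification. Each integrated
#' statistic is a convex combination of its per-wavelength inputs.
#'
#' @param results A `sqrfm_eval` tibble from [evaluate_fingerprints()] (or
#'   any tibble with `sample_id`, `wavelength_nm`, `sf_prime`, `mf`,
#'   `alpha`), covering >= 2 wavelengths.
#' @param entropies Either a tibble with `wavelength_nm` and `entropy`
#'   columns (as from [channel_entropies()]) or a numeric vector named by
#'   wavelength.
#' @param grade_table Threshold table, by default [sqrfm_grade_table()].
#' @return A tibble of class `sqrfm_integration`, one row per sample, with
#'   `sf_prime`, `mf`, `alpha`, `grade` and the weight table attached as
#'   attribute `"weights"`.
#' @export
integrate_channels <- function(results, entropies,
                               grade_table = sqrfm_grade_table()) {
  results <- as_tibble(results)
  if (is.numeric(entropies)) {
    entropies <- tibble(wavelength_nm = as.numeric(names(entropies)),
                        entropy = as.numeric(entropies))
  }
  wl <- sort(unique(results$wavelength_nm))
  if (length(wl) < 2) abort("need results at >= 2 wavelengths")
  if (!setequal(wl, entropies$wavelength_nm)) {
    abort("entropies must cover exactly the wavelengths present in results")
  }
  entropies <- entropies[match(wl, entropies$wavelength_nm), ]
  wts <- tibble(wavelength_nm = wl,
                entropy = entropies$entropy,
                weight = entropy_weights(entropies$entropy))
  counts <- dplyr::count(results, .data$sample_id)
  if (any(counts$n != length(wl))) {
    abort("every sample must be evaluated at every wavelength")
  }
  out <- results |>
    dplyr::inner_join(wts, by = "wavelength_nm") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      sf_prime = sum(.data$weight * .data$sf_prime),
      mf = sum(.data$weight * .data$mf),
      alpha = sum(.data$weight * .data$alpha),
      .groups = "drop") |>
    dplyr::mutate(grade = sqrfm_grade(.data$sf_prime, .data$mf, .data$alpha,
                                      grade_table))
  attr(out, "weights") <- wts
  class(out) <- c("sqrfm_integration", class(out))
  out
}
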