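#' Configuration for the synthetic batch generator
#'
#' Defaults emulate a multi-wavelength HPLC fingerprint study of a herbal
#' preparation: 27 production batches, five detection wavelengths with
#' 39/31/15/15/9 co-possessing peaks, 1.2 g weighed-in samples, retention
#' times spread over a 90-minute gradient. Batch-to-batch content variation
#' is a per-sample multiplicative factor `c_s` (lognormal, sdlog
#' `content_sdlog`) acting on every peak, which drives MF; peak-level
#' lognormal noise (`ratio_noise`, the sd of log areas) perturbs the ratio
#' fingerprint and drives SF' and alpha; `mass_cv` jitters the weighed-in
#' mass.
#'
#' @param n_samples Number of batch samples (default 27).
#' @param wavelengths Detection wavelengths in nm.
#' @param n_peaks Co-possessing peak count per wavelength (recycled).
#' @param sample_mass_g Nominal weighed-in mass in grams (default 1.2).
#' @param mass_cv Coefficient of variation of the weighed-in mass
#'   (default 0.005).
#' @param content_sdlog sdlog of the per-sample content factor `c_s`
#'   (default 0.12; ~ +/- 25 percent content spread at 2 sd).
#' @param content_scale Optional explicit vector of `c_s`, one per sample,
#'   overriding the lognormal draw (e.g. a calibration sweep).
#' @param ratio_noise sd of the per-peak lognormal noise on log areas
#'   (default 0.05, matching a few-percent relative peak-area spread).
#' @param rt_range Retention-time window in minutes.
#' @param area_meanlog,area_sdlog Lognormal parameters of the reference peak
#'   areas.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 27,
                       wavelengths = c(250, 276, 330, 360, 375),
                       n_peaks = c(39, 31, 15, 15, 9),
                       sample_mass_g = 1.2,
                       mass_cv = 0.005,
                       content_sdlog = 0.12,
                       content_scale = NULL,
                       ratio_noise = 0.05,
                       rt_range = c(2, 90),
                       area_meanlog = log(500),
                       area_sdlog = 1) {
  n_peaks <- rep_len(n_peaks, length(wavelengths))
  if (!is.null(content_scale) && length(content_scale) != n_samples) {
    abort("content_scale must have one value per sample")
  }
  structure(list(n_samples = n_samples, wavelengths = wavelengths,
                 n_peaks = n_peaks, sample_mass_g = sample_mass_g,
                 mass_cv = mass_cv, content_sdlog = content_sdlog,
                 content_scale = content_scale, ratio_noise = ratio_noise,
                 rt_range = rt_range, area_meanlog = area_meanlog,
                 area_sdlog = area_sdlog),
            class = "sim_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Simulate a batch of multi-wavelength peak tables
#'
#' Generates a reference profile per wavelength (lognormal peak areas at
#' sorted uniform retention times), then sample areas
#' \eqn{x_i = c_s \, y_i \, e^{\varepsilon_i}} with
#' \eqn{\varepsilon_i \sim N(0, \texttt{ratio\_noise}^2)} and the per-sample
#' content factor \eqn{c_s} from the configuration. With `ratio_noise = 0`
#' and `c_s = 1` every sample reproduces the reference exactly. Output is
#' bit-identical for a fixed seed, and the generating profile is recorded so
#' that realised statistics can be compared with ground truth (downstream
#' evaluation recomputes the RFP as the batch column means, as in practice).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for reproducibility.
#' @return A list: `peaks` (standard peak-table tibble for all samples),
#'   `rfp_true` (the generating reference profile as a peak table), `truth`
#'   (per-sample tibble with `c_s`, mass and realised per-wavelength
#'   `sf_prime`, `mf`, `alpha` against the generating reference),
#'   `config`, `seed`.
#' @export
simulate_batch <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    ids <- sprintf("S%02d", seq_len(config$n_samples))
    c_s <- config$content_scale %||%
      stats::rlnorm(config$n_samples, 0, config$content_sdlog)
    masses <- config$sample_mass_g *
      (1 + stats::rnorm(config$n_samples, 0, config$mass_cv))
    masses <- pmax(masses, 0.1 * config$sample_mass_g)
    rfp_rows <- purrr::map2(config$wavelengths, config$n_peaks,
      function(wl, np) {
        tibble(sample_id = "RFP", batch_id = "RFP", wavelength_nm = wl,
               peak_id = seq_len(np),
               rt_min = sort(stats::runif(np, config$rt_range[1],
                                          config$rt_range[2])),
               area = stats::rlnorm(np, config$area_meanlog,
                                    config$area_sdlog),
               sample_mass_g = config$sample_mass_g)
      })
    rfp_true <- dplyr::bind_rows(rfp_rows)
    peaks <- purrr::map(seq_len(config$n_samples), function(s) {
      dplyr::mutate(rfp_true,
                    sample_id = ids[s],
                    batch_id = ids[s],
                    area = c_s[s] * .data$area *
                      exp(stats::rnorm(dplyr::n(), 0, config$ratio_noise)),
                    sample_mass_g = masses[s])
    }) |> dplyr::bind_rows()
    truth_long <- purrr::map(seq_len(config$n_samples), function(s) {
      purrr::map(config$wavelengths, function(wl) {
        x <- peaks$area[peaks$sample_id == ids[s] &
                          peaks$wavelength_nm == wl]
        y <- rfp_true$area[rfp_true$wavelength_nm == wl]
        f <- config$sample_mass_g / masses[s]
        sfp <- sqrfm_sf_prime(x, y)
        tibble(sample_id = ids[s], wavelength_nm = wl, c_s = c_s[s],
               sample_mass_g = masses[s], sf_prime = sfp,
               mf = sqrfm_mf(x, y, f), alpha = sqrfm_alpha(sfp))
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    list(peaks = validate_peak_table(peaks), rfp_true = rfp_true,
         truth = truth_long, config = config, seed = seed)
  })
}

#' Simulate an activity variable coupled to peak areas
#'
#' Builds a per-sample activity (e.g. an EC50) linearly coupled to the peak
#' areas at one wavelength:
#' \eqn{EC_{50,s} = \beta_0 + \sum_k \beta_k \, x_{sk} + N(0, \sigma^2)}.
#' With `noise_sd = 0` a full-component PLS refit recovers `beta` exactly on
#' full-rank designs.
#'
#' @param peaks A peak table (e.g. `simulate_batch()$peaks`).
#' @param beta Coefficient vector, one per peak at `wavelength` (sparse
#'   vectors emulate a few active constituents).
#' @param intercept Baseline activity (default 0.65 mg/ml).
#' @param noise_sd Residual sd (default 0.01).
#' @param seed Integer seed.
#' @param wavelength Wavelength whose peak areas drive the activity
#'   (default: the lowest present).
#' @return A list: `x` (samples x peaks area matrix), `ec50` (activity
#'   vector), `beta`, `intercept`, `sample_ids`.
#' @export
simulate_activity <- function(peaks, beta, intercept = 0.65,
                              noise_sd = 0.01, seed = 1,
                              wavelength = NULL) {
  peaks <- validate_peak_table(peaks)
  wavelength <- wavelength %||% min(peaks$wavelength_nm)
  pw <- peaks[peaks$wavelength_nm == wavelength, ]
  x <- pw |>
    dplyr::select(dplyr::all_of(c("sample_id", "peak_id", "area"))) |>
    tidyr::pivot_wider(names_from = "peak_id", values_from = "area",
                       names_prefix = "x")
  ids <- x$sample_id
  xm <- as.matrix(x[, -1])
  rownames(xm) <- ids
  if (length(beta) != ncol(xm)) {
    abort("beta must have one coefficient per peak")
  }
  with_seed(seed, {
    ec50 <- intercept + drop(xm %*% beta) +
      stats::rnorm(nrow(xm), 0, noise_sd)
    list(x = xm, ec50 = ec50, beta = beta, intercept = intercept,
         sample_ids = ids)
  })
}
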