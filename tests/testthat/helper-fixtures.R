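# small programmatic fixtures shared across test files

# peak table for one wavelength from a named list of area vectors;
# retention times default to 1, 2, ... so tables are pre-aligned
make_peaks <- function(areas, wavelength = 250, rt = NULL, mass = 1.2,
                       batch = NULL) {
  dplyr::bind_rows(purrr::imap(areas, function(a, id) {
    tibble::tibble(
      sample_id = id,
      batch_id = if (is.null(batch)) id else batch,
      wavelength_nm = wavelength,
      peak_id = seq_along(a),
      rt_min = rt %||% seq_along(a),
      area = a,
      sample_mass_g = if (length(mass) > 1) mass[[id]] else mass)
  }))
}

write_peaks_csv <- function(peaks, path = withr::local_tempfile(
                              fileext = ".csv", .local_envir = parent.frame())) {
  readr::write_csv(peaks, path)
  path
}

# random strictly positive fingerprint pair
random_pair <- function(n = 8, f = 1) {
  fingerprint_pair(stats::rlnorm(n, 3, 0.6), stats::rlnorm(n, 3, 0.6), f = f)
}

`%||%` <- rlang::`%||%`
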