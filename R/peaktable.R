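#' Peak-table column schema
#'
#' Long-form peak tables are the package's central data structure: one row per
#' integrated chromatographic peak, for one sample at one detection
#' wavelength. All ingest and simulation functions produce this layout.
#'
#' @format The required columns are
#' \describe{
#'   \item{sample_id}{character, sample / batch label.}
#'   \item{batch_id}{character, manufacturing batch number (free text).}
#'   \item{wavelength_nm}{integer, detection wavelength in nm.}
#'   \item{peak_id}{integer, peak index within a wavelength (1..n after
#'     alignment).}
#'   \item{rt_min}{numeric, retention time in minutes (non-negative).}
#'   \item{area}{numeric, integrated peak area in detector-response units
#'     (non-negative).}
#'   \item{sample_mass_g}{numeric, weighed-in sample mass in grams
#'     (positive).}
#' }
#' @name peak_table_schema
NULL

peak_table_cols <- c("sample_id", "batch_id", "wavelength_nm", "peak_id",
                     "rt_min", "area", "sample_mass_g")

#' Validate a peak table
#'
#' Checks a data frame against the peak-table schema (see
#' [peak_table_schema]): required columns, numeric types, non-negative areas
#' and retention times, positive masses, and uniqueness of
#' `(sample_id, wavelength_nm, peak_id)`.
#'
#' @param peaks A data frame of peaks.
#' @return The validated table as a tibble (invisibly usable in a pipe).
#' @export
validate_peak_table <- function(peaks) {
  missing <- setdiff(peak_table_cols, names(peaks))
  if (length(missing) > 0) {
    abort(paste0("peak table is missing column(s): ",
                 paste(missing, collapse = ", ")), class = "sqrfm_schema_error")
  }
  peaks <- as_tibble(peaks)
  num_cols <- c("wavelength_nm", "peak_id", "rt_min", "area", "sample_mass_g")
  for (cl in num_cols) {
    v <- peaks[[cl]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
      abort(paste0("column '", cl, "' must be numeric and complete; ",
                   "offending row(s): ", paste(head(bad, 5), collapse = ", ")),
            class = "sqrfm_schema_error")
    }
  }
  check_rows <- function(bad, what) {
    if (any(bad)) {
      abort(paste0(what, "; offending row(s): ",
                   paste(head(which(bad), 5), collapse = ", ")),
            class = "sqrfm_schema_error")
    }
  }
  check_rows(peaks$area < 0, "peak areas must be >= 0")
  check_rows(peaks$rt_min < 0, "retention times must be >= 0")
  check_rows(peaks$sample_mass_g <= 0, "sample masses must be > 0")
  key <- paste(peaks$sample_id, peaks$wavelength_nm, peaks$peak_id)
  check_rows(duplicated(key),
             "duplicated (sample_id, wavelength_nm, peak_id)")
  peaks
}

#' Read a peak table from CSV
#'
#' Reads the standard CSV layout
#' `sample_id,batch_id,wavelength_nm,peak_id,rt_min,area,sample_mass_g`
#' and validates it (see [validate_peak_table()]).
#'
#' @param path Path to a CSV file.
#' @return A validated peak-table tibble.
#' @seealso [write_peak_table()], [align_peaks()]
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "sqrfm_schema_error")
  }
  peaks <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             sample_id = readr::col_character(),
                             batch_id = readr::col_character(),
                             .default = readr::col_double()))
  validate_peak_table(peaks)
}

#' Write a peak table to CSV
#'
#' @param peaks A peak-table tibble.
#' @param path Output path.
#' @return `peaks`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  readr::write_csv(validate_peak_table(peaks), path)
  invisible(peaks)
}

#' Align co-possessing peaks across samples
#'
#' A peak enters the co-possessing set at a wavelength only if it can be
#' matched in every sample of the batch. Matching is greedy on retention
#' time: the sample with the fewest peaks provides the template, candidate
#' pairs within `rt_tol` minutes are accepted closest-first, and ties are
#' broken in favour of the larger peak area. Retained peaks are renumbered
#' `1..n` in retention-time order, consistently across samples; dropped peaks
#' are reported via a message and attached as the `"dropped"` attribute.
#'
#' Alignment is idempotent: running it on an already-aligned table returns
#' the same co-possessing set.
#'
#' @param peaks A peak table covering two or more samples.
#' @param rt_tol Retention-time matching tolerance in minutes (default 0.2).
#' @param quiet Suppress the dropped-peak message.
#' @return The aligned peak table (tibble) with a `"dropped"` attribute
#'   holding the rows that were discarded.
#' @export
align_peaks <- function(peaks, rt_tol = 0.2, quiet = FALSE) {
  peaks <- validate_peak_table(peaks)
  out <- peaks |>
    dplyr::group_by(.data$wavelength_nm) |>
    dplyr::group_split() |>
    purrr::map(align_one_wavelength, rt_tol = rt_tol)
  aligned <- dplyr::bind_rows(purrr::map(out, "aligned"))
  dropped <- dplyr::bind_rows(purrr::map(out, "dropped"))
  if (nrow(aligned) == 0) {
    abort("no co-possessing peaks at any wavelength",
          class = "sqrfm_alignment_error")
  }
  if (!quiet && nrow(dropped) > 0) {
    message(nrow(dropped), " peak row(s) without a match in every sample ",
            "were dropped from the co-possessing set")
  }
  attr(aligned, "dropped") <- dropped
  aligned
}

align_one_wavelength <- function(pw, rt_tol) {
  samples <- split(pw, pw$sample_id)
  if (length(samples) < 2) {
    # single sample: trivially co-possessing with itself
    ref <- samples[[1]][order(samples[[1]]$rt_min), ]
    ref$peak_id <- seq_len(nrow(ref))
    return(list(aligned = ref, dropped = pw[0, ]))
  }
  ref_name <- names(samples)[which.min(vapply(samples, nrow, 0L))]
  ref <- samples[[ref_name]][order(samples[[ref_name]]$rt_min), ]
  n_ref <- nrow(ref)
  # matched[[s]][i] = row index in samples[[s]] matched to template peak i
  matched <- list()
  for (s in names(samples)) {
    if (s == ref_name) {
      matched[[s]] <- seq_len(n_ref)
      next
    }
    cand <- samples[[s]]
    pairs <- expand.grid(i = seq_len(n_ref), j = seq_len(nrow(cand)))
    pairs$d <- abs(ref$rt_min[pairs$i] - cand$rt_min[pairs$j])
    pairs <- pairs[pairs$d <= rt_tol, , drop = FALSE]
    # closest-first greedy; ties broken by larger candidate area
    pairs <- pairs[order(pairs$d, -cand$area[pairs$j]), , drop = FALSE]
    assign <- rep(NA_integer_, n_ref)
    used <- logical(nrow(cand))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (is.na(assign[i]) && !used[j]) {
        assign[i] <- j
        used[j] <- TRUE
      }
    }
    matched[[s]] <- assign
  }
  keep <- Reduce(`&`, purrr::map(matched, ~ !is.na(.x)))
  if (!any(keep)) {
    abort(paste0("zero co-possessing peaks at ", pw$wavelength_nm[1], " nm"),
          class = "sqrfm_alignment_error")
  }
  new_id <- cumsum(keep)  # template is already in RT order
  aligned <- purrr::imap(samples, function(tbl, s) {
    rows <- matched[[s]][keep]
    out <- tbl[rows, ]
    out$peak_id <- new_id[keep]
    out
  })
  aligned_tbl <- dplyr::bind_rows(aligned) |>
    dplyr::arrange(.data$sample_id, .data$peak_id)
  kept_key <- paste(aligned_tbl$sample_id, aligned_tbl$rt_min,
                    aligned_tbl$area)
  dropped <- pw[!(paste(pw$sample_id, pw$rt_min, pw$area) %in% kept_key), ]
  list(aligned = aligned_tbl, dropped = dropped)
}

#' Build the reference fingerprint profile (RFP)
#'
#' The RFP at each wavelength is the arithmetic mean fingerprint of the batch:
#' peak-wise mean areas (and mean retention times) over all samples. Its
#' apparent sample mass `m_R` is, by the package's convention, the mean of the
#' sample masses; pass `m_r` to override.
#'
#' @param peaks An aligned peak table (see [align_peaks()]).
#' @param wavelength Optional wavelength filter (nm); default uses all.
#' @param m_r Optional apparent mass of the RFP in grams; default is the mean
#'   sample mass.
#' @return A peak-table tibble with `sample_id = "RFP"`.
#' @export
build_rfp <- function(peaks, wavelength = NULL, m_r = NULL) {
  peaks <- validate_peak_table(peaks)
  if (!is.null(wavelength)) {
    peaks <- dplyr::filter(peaks, .data$wavelength_nm %in% wavelength)
  }
  if (nrow(peaks) == 0) abort("no peaks at the requested wavelength(s)")
  masses <- dplyr::distinct(peaks, .data$sample_id, .data$sample_mass_g)
  m_r <- m_r %||% mean(masses$sample_mass_g)
  rfp <- peaks |>
    dplyr::group_by(.data$wavelength_nm, .data$peak_id) |>
    dplyr::summarise(rt_min = mean(.data$rt_min), area = mean(.data$area),
                     .groups = "drop") |>
    dplyr::mutate(sample_id = "RFP", batch_id = "RFP",
                  sample_mass_g = m_r) |>
    dplyr::select(dplyr::all_of(peak_table_cols))
  if (any(rfp$area == 0)) {
    abort("RFP contains zero mean peak areas; ratio fingerprints undefined",
          class = "sqrfm_schema_error")
  }
  rfp
}

#' Construct a sample/reference fingerprint pair
#'
#' Bundles the aligned sample peak-area vector `x`, the reference vector `y`
#' and the mass coefficient `f = m_R / m_i` used by the SQRFM statistics.
#'
#' @param x Numeric vector of sample peak areas (non-negative, not all zero).
#' @param y Numeric vector of reference peak areas (strictly positive).
#' @param f Mass coefficient (positive scalar, default 1).
#' @param sample_id,wavelength_nm Optional labels carried through to results.
#' @return An object of class `fingerprint_pair`.
#' @export
fingerprint_pair <- function(x, y, f = 1, sample_id = NA_character_,
                             wavelength_nm = NA_integer_) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 2) {
    abort("x and y must have equal length >= 2")
  }
  if (anyNA(x) || anyNA(y)) abort("x and y must be complete")
  if (any(y <= 0)) abort("all reference areas y must be > 0")
  if (any(x < 0)) abort("sample areas x must be >= 0")
  if (all(x == 0)) abort("sample areas x must not all be zero")
  if (!is.numeric(f) || length(f) != 1 || f <= 0) abort("f must be > 0")
  structure(list(x = x, y = y, n = length(x), f = f,
                 sample_id = sample_id, wavelength_nm = wavelength_nm),
            class = "fingerprint_pair")
}

#' @export
print.fingerprint_pair <- function(x, ...) {
  cat("<fingerprint_pair> n =", x$n, " f =", format(x$f, digits = 4), "\n")
  invisible(x)
}

#' Extract fingerprint pairs from a peak table
#'
#' Pairs every sample in `peaks` with the reference profile `rfp`, one pair
#' per sample and wavelength, computing the mass coefficient
#' `f = m_R / m_i` from the stored sample masses.
#'
#' @param peaks Aligned peak table of the batch samples.
#' @param rfp Reference profile as returned by [build_rfp()].
#' @return A list of [fingerprint_pair()] objects.
#' @export
fingerprint_pairs <- function(peaks, rfp) {
  peaks <- validate_peak_table(peaks)
  rfp <- validate_peak_table(rfp)
  groups <- peaks |>
    dplyr::group_by(.data$sample_id, .data$wavelength_nm) |>
    dplyr::group_split()
  purrr::map(groups, function(g) {
    r <- rfp[rfp$wavelength_nm == g$wavelength_nm[1], ]
    r <- r[order(r$peak_id), ]
    g <- g[order(g$peak_id), ]
    if (!identical(as.integer(g$peak_id), as.integer(r$peak_id))) {
      abort("sample and RFP peak ids do not match; align the table first")
    }
    fingerprint_pair(g$area, r$area, f = r$sample_mass_g[1] / g$sample_mass_g[1],
                     sample_id = g$sample_id[1],
                     wavelength_nm = g$wavelength_nm[1])
  })
}

#' Fingerprint method-validation metrics (RRT / RPA)
#'
#' For replicate injections, computes each peak's relative retention time
#' (RRT, retention time divided by that of the reference peak) and relative
#' peak area (RPA), then their percentage relative standard deviations across
#' replicates (sample standard deviation over mean, x100). These are the
#' conventional repeatability / precision / stability summaries for
#' fingerprint methodology validation.
#'
#' @param replicates Peak table whose `sample_id` identifies replicate
#'   injections (one wavelength at a time or several; the reference peak id
#'   applies per wavelength).
#' @param ref_peak Integer peak id of the reference peak.
#' @return A list of class `fp_validation`: `$ratios`, a long tibble of
#'   per-replicate RRT/RPA, and `$summary`, a per-peak tibble with
#'   `rsd_rrt` and `rsd_rpa` (percent).
#' @export
validation_metrics <- function(replicates, ref_peak) {
  replicates <- validate_peak_table(replicates)
  ref <- replicates |>
    dplyr::filter(.data$peak_id == ref_peak) |>
    dplyr::select(dplyr::all_of(c("sample_id", "wavelength_nm")),
                  ref_rt = "rt_min", ref_area = "area")
  n_rep <- dplyr::n_distinct(replicates$sample_id)
  if (n_rep < 2) abort("need >= 2 replicate injections")
  by_wl <- dplyr::count(replicates, .data$wavelength_nm,
                        wt = as.integer(.data$peak_id == ref_peak))
  expected <- dplyr::n_distinct(replicates$wavelength_nm) * n_rep
  if (sum(by_wl$n) != expected) {
    abort(paste0("reference peak ", ref_peak,
                 " missing in at least one replicate"))
  }
  ratios <- replicates |>
    dplyr::inner_join(ref, by = c("sample_id", "wavelength_nm")) |>
    dplyr::mutate(rrt = .data$rt_min / .data$ref_rt,
                  rpa = .data$area / .data$ref_area) |>
    dplyr::select(dplyr::all_of(c("sample_id", "wavelength_nm", "peak_id",
                                  "rrt", "rpa")))
  rsd <- function(v) 100 * sd(v) / mean(v)
  summary <- ratios |>
    dplyr::group_by(.data$wavelength_nm, .data$peak_id) |>
    dplyr::summarise(mean_rrt = mean(.data$rrt), rsd_rrt = rsd(.data$rrt),
                     mean_rpa = mean(.data$rpa), rsd_rpa = rsd(.data$rpa),
                     .groups = "drop")
  structure(list(ratios = ratios, summary = summary, ref_peak = ref_peak),
            class = "fp_validation")
}

#' @export
print.fp_validation <- function(x, ...) {
  cat("<fp_validation> reference peak", x$ref_peak, "\n")
  cat("  max RSD(RRT):", format(max(x$summary$rsd_rrt), digits = 3), "%\n")
  cat("  max RSD(RPA):", format(max(x$summary$rsd_rpa), digits = 3), "%\n")
  invisible(x)
}
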