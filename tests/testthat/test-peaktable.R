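test_that("CSV round trip preserves well-formed peak tables", {
  pt <- make_peaks(list(A = c(2, 4, 6, 8)))
  path <- write_peaks_csv(pt)
  got <- read_peak_table(path)
  expect_equal(nrow(got), 4)
  expect_equal(got$area, pt$area)
  expect_equal(got$sample_id, pt$sample_id)

  out <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(got, out)
  expect_equal(read_peak_table(out), got)
})

test_that("schema violations are rejected with informative errors", {
  pt <- make_peaks(list(A = c(2, 4)))

  bad_area <- pt
  bad_area$area[2] <- -1
  expect_error(validate_peak_table(bad_area), class = "sqrfm_schema_error")
  expect_error(read_peak_table(write_peaks_csv(bad_area)), "row")

  dup <- pt
  dup$peak_id <- c(1, 1)
  expect_error(read_peak_table(write_peaks_csv(dup)), "duplicated")

  expect_error(validate_peak_table(pt[, -3]), "missing column")
  bad_mass <- pt
  bad_mass$sample_mass_g <- 0
  expect_error(validate_peak_table(bad_mass), "masses")
  expect_error(read_peak_table("no/such/file.csv"), "not found")
})

test_that("alignment keeps only peaks matched in every sample", {
  # identical RT grids: everything retained
  same <- make_peaks(list(A = c(1, 2, 3), B = c(2, 4, 6)))
  al <- align_peaks(same, quiet = TRUE)
  expect_equal(nrow(al), 6)
  expect_equal(sort(unique(al$peak_id)), 1:3)

  # a peak present in only one sample is dropped
  pt <- dplyr::bind_rows(
    make_peaks(list(A = c(1, 2, 3)), rt = c(1, 5, 9)),
    make_peaks(list(B = c(2, 4)), rt = c(1.05, 9.1)))
  expect_message(al <- align_peaks(pt, rt_tol = 0.2), "dropped")
  expect_equal(dplyr::n_distinct(al$peak_id), 2)
  expect_equal(nrow(attr(al, "dropped")), 1)
  expect_equal(attr(al, "dropped")$rt_min, 5)

  # nothing in common at all
  far <- dplyr::bind_rows(make_peaks(list(A = c(1, 2)), rt = c(1, 2)),
                          make_peaks(list(B = c(1, 2)), rt = c(50, 60)))
  expect_error(align_peaks(far, quiet = TRUE), class = "sqrfm_alignment_error")
})

test_that("jittered grids are fully retained and renumbered consistently", {
  # brute-force oracle: with jitter well under rt_tol every template peak has
  # a unique match in every sample, so the co-possessing count equals the
  # smallest per-sample peak count
  set.seed(11)
  base_rt <- c(3, 8, 15, 24, 40)
  pt <- dplyr::bind_rows(
    make_peaks(list(A = stats::rlnorm(5, 4)), rt = base_rt),
    make_peaks(list(B = stats::rlnorm(5, 4)),
               rt = base_rt + stats::runif(5, -0.05, 0.05)),
    make_peaks(list(C = stats::rlnorm(5, 4)),
               rt = base_rt + stats::runif(5, -0.05, 0.05)))
  al <- align_peaks(pt, rt_tol = 0.2, quiet = TRUE)
  expect_equal(dplyr::n_distinct(al$peak_id), 5)
  expect_equal(nrow(al), 15)
  # every sample exposes the same ordered peak set, numbered 1..n by RT
  per_sample <- split(al, al$sample_id)
  for (tbl in per_sample) {
    expect_equal(sort(tbl$peak_id), 1:5)
    expect_equal(tbl$peak_id[order(tbl$rt_min)], 1:5)
  }
})

test_that("alignment is idempotent", {
  set.seed(12)
  pt <- dplyr::bind_rows(
    make_peaks(list(A = stats::rlnorm(4, 4)), rt = c(2, 7, 7.4, 20)),
    make_peaks(list(B = stats::rlnorm(5, 4)), rt = c(2.1, 6.9, 7.5, 20.1, 33)))
  al1 <- align_peaks(pt, quiet = TRUE)
  al2 <- align_peaks(al1, quiet = TRUE)
  expect_equal(
    dplyr::arrange(tibble::as_tibble(al2), sample_id, peak_id),
    dplyr::arrange(tibble::as_tibble(al1), sample_id, peak_id),
    ignore_attr = TRUE)
})

test_that("RFP is the peak-wise mean profile with mean apparent mass", {
  pt <- make_peaks(list(A = c(2, 4), B = c(4, 8)), mass = list(A = 1.0, B = 1.4))
  rfp <- build_rfp(pt)
  expect_equal(rfp$area, c(3, 6))
  expect_equal(unique(rfp$sample_mass_g), 1.2)
  expect_equal(unique(rfp$sample_id), "RFP")

  # single sample: RFP equals that sample
  one <- make_peaks(list(A = c(5, 7, 9)))
  expect_equal(build_rfp(one)$area, c(5, 7, 9))

  # m_R override
  expect_equal(unique(build_rfp(pt, m_r = 2)$sample_mass_g), 2)

  # 27 simulated samples match an independent column-mean oracle
  sim <- simulate_batch(sim_config(n_samples = 27, n_peaks = 6,
                                   wavelengths = 250), seed = 4)
  rfp27 <- build_rfp(sim$peaks)
  oracle <- tapply(sim$peaks$area, sim$peaks$peak_id, mean)
  expect_equal(rfp27$area[order(rfp27$peak_id)],
               as.numeric(oracle[as.character(1:6)]))

  zero <- make_peaks(list(A = c(0, 1), B = c(0, 3)))
  expect_error(build_rfp(zero), "zero mean")
})

test_that("validation metrics reproduce the sd/mean oracle and its exact cases", {
  # identical replicates: all RSD are zero, reference peak is exactly 1
  reps <- make_peaks(list(r1 = c(10, 20, 5), r2 = c(10, 20, 5)))
  vm <- validation_metrics(reps, ref_peak = 2)
  expect_equal(vm$summary$rsd_rrt, rep(0, 3))
  expect_equal(vm$summary$rsd_rpa, rep(0, 3))
  ref_rows <- vm$ratios[vm$ratios$peak_id == 2, ]
  expect_equal(ref_rows$rrt, rep(1, 2))
  expect_equal(ref_rows$rpa, rep(1, 2))

  # six jittered replicates against an independent sd/mean computation
  set.seed(21)
  areas <- purrr::map(1:6, ~ c(10, 20, 5) * exp(stats::rnorm(3, 0, 0.03)))
  names(areas) <- paste0("r", 1:6)
  rts <- purrr::map(1:6, ~ c(2, 6, 11) + stats::rnorm(3, 0, 0.01))
  reps6 <- dplyr::bind_rows(purrr::imap(areas, function(a, id) {
    make_peaks(setNames(list(a), id), rt = rts[[as.integer(sub("r", "", id))]])
  }))
  vm6 <- validation_metrics(reps6, ref_peak = 1)
  rrt_mat <- sapply(1:6, function(i) rts[[i]] / rts[[i]][1])
  rpa_mat <- sapply(1:6, function(i) areas[[i]] / areas[[i]][1])
  expect_equal(vm6$summary$rsd_rrt,
               apply(rrt_mat, 1, function(v) 100 * sd(v) / mean(v)))
  expect_equal(vm6$summary$rsd_rpa,
               apply(rpa_mat, 1, function(v) 100 * sd(v) / mean(v)))

  # missing reference peak
  broken <- reps[!(reps$sample_id == "r2" & reps$peak_id == 2), ]
  expect_error(validation_metrics(broken, ref_peak = 2), "missing")
})

test_that("RRT and RPA are invariant to global rescaling", {
  reps <- make_peaks(list(r1 = c(10, 20, 5), r2 = c(11, 19, 6)),
                     rt = c(2, 6, 11))
  vm <- validation_metrics(reps, ref_peak = 1)

  scaled <- reps
  scaled$rt_min <- reps$rt_min * 1.7   # uniform RT rescaling
  scaled$area <- reps$area * 250       # global area scaling
  vm_s <- validation_metrics(scaled, ref_peak = 1)
  expect_equal(vm_s$ratios$rrt, vm$ratios$rrt)
  expect_equal(vm_s$ratios$rpa, vm$ratios$rpa)
})
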