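make_xy <- function(n, p, beta = NULL, noise = 0.1, seed = 61) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- beta %||% stats::rnorm(p)
  y <- drop(x %*% beta) + stats::rnorm(n, 0, noise)
  list(x = x, y = y, beta = beta)
}

test_that("full-component PLS reproduces ordinary least squares", {
  for (seed in 61:63) {
    d <- make_xy(n = 12, p = 4, seed = seed)
    fit <- fit_plsr(d$x, d$y, ncomp = 4)
    ols <- lm(d$y ~ d$x)
    expect_equal(unname(fit$coefficients), unname(coef(ols)[-1]),
                 tolerance = 1e-10)
    expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
    expect_equal(fit$fitted, unname(fitted(ols)), tolerance = 1e-10)
  }
})

test_that("an exactly linear response is fitted with zero residuals", {
  d <- make_xy(n = 10, p = 3, beta = c(1, -2, 0.5), noise = 0)
  fit <- fit_plsr(d$x, d$y, ncomp = 3)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), c(1, -2, 0.5), tolerance = 1e-9)
  expect_equal(glance(fit)$r.squared, 1, tolerance = 1e-12)
})

test_that("fits and cross-validation are invariant to sample order", {
  d <- make_xy(n = 14, p = 6)
  perm <- sample(14)
  fit1 <- fit_plsr(d$x, d$y, ncomp = 3)
  fit2 <- fit_plsr(d$x[perm, ], d$y[perm], ncomp = 3)
  expect_equal(fit1$coefficients, fit2$coefficients)
  expect_equal(fit1$intercept, fit2$intercept)

  cv1 <- plsr_loo(d$x, d$y, ncomp = 3)
  cv2 <- plsr_loo(d$x[perm, ], d$y[perm], ncomp = 3)
  expect_equal(cv2$predicted, cv1$predicted[perm])
})

test_that("PLS predictions agree with an independent library implementation", {
  d <- make_xy(n = 12, p = 5, seed = 64)
  for (nc in 1:3) {
    mine <- fit_plsr(d$x, d$y, ncomp = nc)
    ref <- mixOmics::pls(d$x, d$y, ncomp = nc, scale = FALSE,
                         mode = "regression")
    ref_pred <- predict(ref, d$x)$predict[, 1, nc]
    expect_equal(unname(predict(mine, d$x)), unname(ref_pred),
                 tolerance = 1e-8)
  }
})

test_that("leave-one-out predictions match a hand-rolled refit oracle", {
  d <- make_xy(n = 8, p = 2, seed = 65)
  cv <- plsr_loo(d$x, d$y, ncomp = 2)
  # at full rank each LOO refit is the OLS fit on the remaining samples
  oracle <- vapply(1:8, function(i) {
    fit <- lm(y ~ ., data = data.frame(y = d$y[-i], d$x[-i, ]))
    unname(predict(fit, data.frame(d$x)[i, ]))
  }, numeric(1))
  expect_equal(cv$predicted, oracle, tolerance = 1e-9)
  expect_equal(cv$re, 100 * (oracle - d$y) / d$y, tolerance = 1e-9)

  # perfect linear data: every relative error is zero
  dd <- make_xy(n = 9, p = 2, beta = c(1, 2), noise = 0, seed = 66)
  dd$y <- dd$y + 5  # keep measured values away from zero
  cv0 <- plsr_loo(dd$x, dd$y, ncomp = 2)
  expect_equal(max(abs(cv0$re)), 0, tolerance = 1e-8)
})

test_that("relative errors and singular-point flags follow their definitions", {
  expect_equal(round(relative_error(0.513, 0.446), 1), 15.0)
  expect_equal(round(relative_error(0.434, 0.522), 1), -16.9)
  expect_equal(relative_error(2, 2), 0)
  expect_error(relative_error(1, 0), "nonzero")

  re <- c(8.0, 26.4, -23.8, 16.1, -14.3, 18.6)
  expect_equal(flag_singular_points(re, 20), c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_false(any(flag_singular_points(re, 30)))
  expect_equal(flag_singular_points(c(0, 1e-9, -2), 0), c(FALSE, TRUE, TRUE))
})

test_that("calibration diagnostics match the closed-form OLS oracle", {
  # lm() warns on the exact-identity fit; the zero SEs are the point here
  perfect <- suppressWarnings(calibration_diagnostics(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$intercept, 0)
  expect_equal(perfect$slope_se, 0)
  expect_equal(perfect$intercept_se, 0)

  set.seed(67)
  m <- stats::runif(10, 0.4, 0.9)
  p <- 0.9 * m + 0.05 + stats::rnorm(10, 0, 0.02)
  got <- calibration_diagnostics(p, m)
  sxx <- sum((m - mean(m))^2)
  b <- sum((m - mean(m)) * (p - mean(p))) / sxx
  a <- mean(p) - b * mean(m)
  res <- p - (a + b * m)
  s2 <- sum(res^2) / (10 - 2)
  expect_equal(got$slope, b)
  expect_equal(got$intercept, a)
  expect_equal(got$slope_se, sqrt(s2 / sxx))
  expect_equal(got$intercept_se, sqrt(s2 * (1 / 10 + mean(m)^2 / sxx)))

  # exclusion flags drop samples before fitting
  m2 <- c(m, 10); p2 <- c(p, 0)
  excl <- c(rep(FALSE, 10), TRUE)
  expect_equal(calibration_diagnostics(p2, m2, exclude = excl)$slope, b)
})

test_that("the spectrum-effect workflow flags outliers and refits without them", {
  # activity driven by two peaks; one sample's measured value is corrupted
  d <- make_xy(n = 16, p = 5, beta = c(0.5, -0.4, 0, 0, 0), noise = 0.01,
               seed = 68)
  y <- d$y + 5
  y_bad <- y
  y_bad[7] <- y[7] * 1.4
  se <- spectrum_effect(d$x, y_bad, ncomp = 2)
  expect_true(se$cv$singular[7])
  expect_equal(sum(se$cv$singular), 1)
  expect_equal(which.max(abs(se$cv$cv_re)), 7L)
  # the final model is fitted without the corrupted sample and calibrates well
  expect_equal(se$diagnostics$n, 15)
  expect_gt(se$diagnostics$r, 0.95)
  expect_equal(glance(se)$n_singular, 1)
  expect_s3_class(autoplot(se), "ggplot")
  expect_equal(nrow(augment(se)), 16)
  # tidy() exposes the model equation terms
  expect_equal(nrow(tidy(se)), 6)
})

test_that("component selection minimises leave-one-out PRESS", {
  d <- make_xy(n = 12, p = 6, beta = c(2, -2, rep(0, 4)), noise = 0.05,
               seed = 69)
  nc <- select_ncomp(d$x, d$y)
  press <- attr(nc, "press")
  expect_equal(which.min(press), as.integer(nc))
  expect_lte(nc, 6)
  # PRESS evaluated by an independent loop for the chosen count
  cv <- plsr_loo(d$x, d$y, as.integer(nc))
  expect_equal(press[nc], sum((cv$predicted - cv$measured)^2))
})
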