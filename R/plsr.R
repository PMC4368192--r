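#' Fit a PLS1 (partial least squares) regression
#'
#' NIPALS partial least squares with a single response, the standard latent
#' variable regression for spectrum-effect modelling where the predictor
#' matrix (peak areas) has many more columns than rows. Predictors are
#' mean-centred; unit-variance scaling is off by default so coefficients stay
#' on the raw peak-area scale. With `ncomp` equal to the rank of the centred
#' predictor matrix, PLS predictions coincide with ordinary least squares.
#' The fit is deterministic for fixed input and invariant to sample order.
#'
#' @param x Numeric matrix or data frame of predictors (samples x peaks), no
#'   missing values.
#' @param y Numeric response vector (e.g. measured EC50).
#' @param ncomp Number of latent components, at most
#'   `min(n_samples - 1, n_peaks)`.
#' @param scale Also scale predictors to unit variance (default `FALSE`).
#' @return An object of class `plsr_fit` with elements `coefficients` (on
#'   the original predictor scale), `intercept`, `ncomp`, `fitted`,
#'   `residuals`, `scores`, `loadings`, `weights`.
#' @seealso [plsr_loo()], [spectrum_effect()]
#' @export
fit_plsr <- function(x, y, ncomp, scale = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) abort("nrow(x) must equal length(y)")
  if (anyNA(x) || anyNA(y)) abort("x and y must be complete")
  ncomp <- as.integer(ncomp)
  max_comp <- min(nrow(x) - 1L, ncol(x))
  if (ncomp < 1 || ncomp > max_comp) {
    abort(paste0("ncomp must be in 1..", max_comp))
  }
  xm <- colMeans(x)
  xs <- if (scale) apply(x, 2, sd) else rep(1, ncol(x))
  if (any(xs == 0)) abort("constant predictor column cannot be scaled")
  ym <- mean(y)
  E <- sweep(sweep(x, 2, xm), 2, xs, `/`)
  f <- y - ym
  n <- nrow(x); p <- ncol(x)
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) {
      abort(paste0("predictor matrix rank is below ncomp = ", ncomp))
    }
    w <- w / wn
    t <- drop(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) abort(paste0("degenerate component ", a))
    p_a <- drop(crossprod(E, t)) / tt
    q[a] <- sum(f * t) / tt
    E <- E - tcrossprod(t, p_a)
    f <- f - q[a] * t
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t
  }
  b_scaled <- drop(W %*% solve(crossprod(P, W), q))
  coefficients <- b_scaled / xs
  names(coefficients) <- colnames(x) %||% paste0("x", seq_len(p))
  intercept <- ym - sum(xm * coefficients)
  fitted <- drop(x %*% coefficients) + intercept
  structure(list(coefficients = coefficients, intercept = intercept,
                 ncomp = ncomp, fitted = fitted, residuals = y - fitted,
                 scores = Tm, loadings = P, weights = W,
                 x_center = xm, x_scale = xs, y_center = ym,
                 n = n, p = p),
            class = "plsr_fit")
}

#' @export
print.plsr_fit <- function(x, ...) {
  cat("<plsr_fit>", x$ncomp, "component(s),", x$n, "samples,",
      x$p, "predictors\n")
  cat("  RMSE:", format(sqrt(mean(x$residuals^2)), digits = 4), "\n")
  invisible(x)
}

#' @export
predict.plsr_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$coefficients) + object$intercept
}

#' @export
tidy.plsr_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @export
glance.plsr_fit <- function(x, ...) {
  tss <- sum((x$fitted + x$residuals - x$y_center)^2)
  tibble(ncomp = x$ncomp, n = x$n, p = x$p,
         r.squared = 1 - sum(x$residuals^2) / tss,
         rmse = sqrt(mean(x$residuals^2)))
}

#' Leave-one-out cross-validation of a PLS1 model
#'
#' Full cross-validation: each sample is left out in turn, the model refitted
#' on the rest, and the held-out response predicted. Relative errors are
#' `100 * (predicted - measured) / measured` percent. Results do not depend
#' on sample order.
#'
#' @inheritParams fit_plsr
#' @return A tibble with one row per sample: `measured`, `predicted`, `re`
#'   (percent).
#' @export
plsr_loo <- function(x, y, ncomp, scale = FALSE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (ncomp > min(n - 2L, ncol(x))) {
    abort("ncomp too large for leave-one-out refits")
  }
  pred <- vapply(seq_len(n), function(i) {
    fit <- fit_plsr(x[-i, , drop = FALSE], y[-i], ncomp, scale = scale)
    predict(fit, x[i, , drop = FALSE])
  }, numeric(1))
  tibble(measured = y, predicted = pred,
         re = relative_error(pred, y))
}

#' Choose the PLS component count by LOO PRESS
#'
#' Returns the smallest number of components minimising the leave-one-out
#' predicted residual sum of squares.
#'
#' @inheritParams fit_plsr
#' @param max_comp Largest component count to try (default
#'   `min(n - 2, p, 10)`).
#' @return Integer component count, with the PRESS values as attribute
#'   `"press"`.
#' @export
select_ncomp <- function(x, y, max_comp = NULL, scale = FALSE) {
  x <- as.matrix(x)
  max_comp <- max_comp %||% min(nrow(x) - 2L, ncol(x), 10L)
  press <- vapply(seq_len(max_comp), function(a) {
    cv <- plsr_loo(x, y, a, scale = scale)
    sum((cv$predicted - cv$measured)^2)
  }, numeric(1))
  best <- which.min(press)
  structure(as.integer(best), press = press)
}

#' Relative error in percent
#'
#' `100 * (predicted - measured) / measured`.
#'
#' @param predicted,measured Numeric vectors.
#' @return Percent relative errors.
#' @examples
#' relative_error(0.513, 0.446)  # 15.0
#' @export
relative_error <- function(predicted, measured) {
  if (any(measured == 0)) abort("measured values must be nonzero")
  100 * (predicted - measured) / measured
}

#' Flag singular points from cross-validation relative errors
#'
#' A sample whose leave-one-out relative error exceeds the threshold in
#' magnitude is a singular point and is excluded from the final model fit.
#'
#' @param re Percent relative errors from [plsr_loo()].
#' @param threshold Magnitude threshold in percent (default 20).
#' @return Logical vector of flags.
#' @export
flag_singular_points <- function(re, threshold = 20) {
  abs(re) > threshold
}

#' Calibration diagnostics for predicted vs measured activity
#'
#' OLS of predicted on measured values over the non-excluded samples, with
#' standard errors: a slope near 1 and intercept near 0 indicate an unbiased
#' calibration.
#'
#' @param predicted,measured Numeric vectors.
#' @param exclude Logical flags of samples to drop (default none).
#' @return A one-row tibble: `slope`, `intercept`, `slope_se`,
#'   `intercept_se`, `r`, `n`.
#' @export
calibration_diagnostics <- function(predicted, measured, exclude = NULL) {
  exclude <- exclude %||% rep(FALSE, length(predicted))
  keep <- !exclude
  if (sum(keep) < 3) abort("need >= 3 retained samples")
  predicted <- predicted[keep]; measured <- measured[keep]
  fit <- lm(predicted ~ measured)
  s <- summary(fit)$coefficients
  tibble(slope = s[2, 1], intercept = s[1, 1],
         slope_se = s[2, 2], intercept_se = s[1, 2],
         r = cor(measured, predicted), n = sum(keep))
}

#' Spectrum-effect workflow: peaks to activity
#'
#' The full modelling procedure linking fingerprint peak areas to a measured
#' activity: (1) choose the component count by leave-one-out PRESS (unless
#' given); (2) run full cross-validation and flag singular points whose
#' relative error exceeds `re_threshold`; (3) refit on the retained samples;
#' (4) report predictions for all samples from the final model, calibration
#' diagnostics over the retained ones, and the peaks whose coefficients
#' dominate the model.
#'
#' @param x Peak-area matrix (samples x peaks) or data frame; rownames (or
#'   `sample_ids`) label samples.
#' @param y Measured activity vector (e.g. EC50, mg/ml).
#' @param ncomp Component count; chosen by [select_ncomp()] when `NULL`.
#' @param re_threshold Singular-point threshold in percent (default 20).
#' @param coef_fraction Peaks with `|coefficient|` at least this fraction of
#'   the largest magnitude are reported as selected (default 0.05).
#' @param sample_ids Optional sample labels.
#' @param scale Scale predictors to unit variance (default `FALSE`).
#' @return An object of class `spectrum_effect`: a list with `model` (final
#'   [fit_plsr()] on retained samples), `cv` (per-sample tibble: measured,
#'   LOO prediction and RE, singular flag, final-model prediction and RE),
#'   `diagnostics` ([calibration_diagnostics()] over retained samples),
#'   `selected_peaks`, `ncomp`, `re_threshold`.
#' @examples
#' sim <- simulate_batch(sim_config(n_samples = 12, n_peaks = 6,
#'                                  wavelengths = 250), seed = 7)
#' act <- simulate_activity(sim$peaks, beta = c(2e-4, 0, 0, -1e-4, 0, 0),
#'                          noise_sd = 0.005, seed = 8)
#' se <- spectrum_effect(act$x, act$ec50, ncomp = 2)
#' glance(se)
#' @export
spectrum_effect <- function(x, y, ncomp = NULL, re_threshold = 20,
                            coef_fraction = 0.05, sample_ids = NULL,
                            scale = FALSE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  sample_ids <- sample_ids %||% rownames(x) %||% paste0("S", seq_len(nrow(x)))
  ncomp <- ncomp %||% select_ncomp(x, y, scale = scale)
  cv <- plsr_loo(x, y, ncomp, scale = scale)
  flags <- flag_singular_points(cv$re, re_threshold)
  keep <- !flags
  ncomp_final <- min(ncomp, sum(keep) - 1L)
  model <- fit_plsr(x[keep, , drop = FALSE], y[keep], ncomp_final,
                    scale = scale)
  pred_all <- predict(model, x)
  cv_tbl <- tibble(sample_id = sample_ids,
                   measured = y,
                   cv_predicted = cv$predicted,
                   cv_re = cv$re,
                   singular = flags,
                   predicted = pred_all,
                   re = relative_error(pred_all, y))
  diag <- calibration_diagnostics(pred_all, y, exclude = flags)
  cf <- model$coefficients
  sel <- which(abs(cf) >= coef_fraction * max(abs(cf)))
  structure(list(model = model, cv = cv_tbl, diagnostics = diag,
                 selected_peaks = tibble(peak = names(cf)[sel],
                                         index = sel,
                                         coefficient = unname(cf[sel])),
                 ncomp = as.integer(ncomp), re_threshold = re_threshold),
            class = "spectrum_effect")
}

#' @export
print.spectrum_effect <- function(x, ...) {
  cat("<spectrum_effect>", x$ncomp, "component(s);",
      sum(x$cv$singular), "singular point(s) removed at |RE| >",
      x$re_threshold, "%\n")
  cat("  calibration slope:", format(x$diagnostics$slope, digits = 5),
      " intercept:", format(x$diagnostics$intercept, digits = 5), "\n")
  invisible(x)
}

#' @export
tidy.spectrum_effect <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$model$coefficients)),
         estimate = c(x$model$intercept, unname(x$model$coefficients)))
}

#' @export
glance.spectrum_effect <- function(x, ...) {
  d <- x$diagnostics
  tibble(ncomp = x$ncomp, n = length(x$cv$measured),
         n_singular = sum(x$cv$singular),
         slope = d$slope, intercept = d$intercept,
         slope_se = d$slope_se, intercept_se = d$intercept_se, r = d$r)
}

#' @export
augment.spectrum_effect <- function(x, ...) {
  x$cv
}

#' Plot predicted vs measured activity
#'
#' Scatter of final-model predictions against measured values with the
#' calibration line and the identity line; singular points are marked.
#'
#' @param object A [spectrum_effect()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectrum_effect <- function(object, ...) {
  df <- object$cv
  d <- object$diagnostics
  ggplot2::ggplot(df, ggplot2::aes(.data$measured, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_abline(slope = d$slope, intercept = d$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$singular), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4),
                                name = "singular") +
    ggplot2::labs(x = "measured activity", y = "predicted activity") +
    ggplot2::theme_minimal()
}
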