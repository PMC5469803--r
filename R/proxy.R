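# Multiple-linear-regression proxy models: fit, cross-validated coefficient
# ensembles, prediction of molecular indices from optics, instrument
# intercalibration and measured-vs-modeled comparison.

#' Fit a proxy multiple linear regression
#'
#' Ordinary least squares of one molecular index on a set of optical
#' predictors, reporting raw and standardised (beta) coefficients, the
#' percent standard error of estimate (100 RMSE / mean(y)), R-squared and
#' the overall F-test p-value.
#'
#' @param data Data frame holding response and predictors.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor columns (default the
#'   carbon-specific humic-like and protein-like peaks plus potential
#'   temperature).
#' @return Object of class `proxy_fit`.
#' @export
fit_proxy_model <- function(data, response,
                            predictors = c("peak_c_star", "peak_t_star",
                                           "theta_c")) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(predictors %in% names(data)))
  df <- data[c(response, predictors)]
  stopifnot(nrow(df) >= length(predictors) + 2)
  X <- as.matrix(df[predictors])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    bad <- predictors[qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1]
    stop(sprintf("rank-deficient design; collinear columns: %s",
                 paste(bad, collapse = ", ")))
  }
  fml <- stats::reformulate(predictors, response)
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)
  y <- df[[response]]
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  beta <- stats::coef(fit)[predictors] *
    apply(X, 2, stats::sd) / stats::sd(y)
  fstat <- sm$fstatistic
  p_overall <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(fit = fit,
                 response = response,
                 predictors = predictors,
                 coefficients = stats::coef(fit),
                 beta = beta,
                 see_pct = 100 * rmse / mean(y),
                 r_squared = sm$r.squared,
                 p_value = unname(p_overall),
                 n = nrow(df)),
            class = "proxy_fit")
}

#' @export
print.proxy_fit <- function(x, ...) {
  cat(sprintf("<proxy_fit> %s ~ %s (n = %d)\n", x$response,
              paste(x$predictors, collapse = " + "), x$n))
  print(round(x$coefficients, 4))
  cat(sprintf("  R2 = %.3f, SEE = %.2f%%, p = %.3g\n",
              x$r_squared, x$see_pct, x$p_value))
  invisible(x)
}

#' Tidy a proxy fit
#' @param x A `proxy_fit`.
#' @param ... Unused.
#' @return Tibble with term, estimate, std.error, statistic, p.value, beta.
#' @exportS3Method generics::tidy
tidy.proxy_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm),
                 estimate = sm[, 1], std.error = sm[, 2],
                 statistic = sm[, 3], p.value = sm[, 4],
                 beta = c(NA_real_, x$beta)[match(rownames(sm),
                         c("(Intercept)", x$predictors))])
}

#' Glance at a proxy fit
#' @param x A `proxy_fit`.
#' @param ... Unused.
#' @return One-row tibble: r.squared, see.pct, p.value, nobs.
#' @exportS3Method generics::glance
glance.proxy_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, see.pct = x$see_pct,
                 p.value = x$p_value, nobs = x$n)
}

#' Cross-validated coefficient ensemble
#'
#' Repeatedly splits the samples into a training fraction (rows drawn
#' without replacement, floor(train_fraction * n)) and a held-out
#' remainder, refits the proxy regression on each training set and records
#' the coefficients and the held-out error. Reports per-coefficient means
#' and standard deviations over the repetitions and the mean held-out
#' error.
#'
#' @inheritParams fit_proxy_model
#' @param train_fraction Fraction of samples used for fitting (default
#'   0.8; n = 29 gives 23 train / 6 test).
#' @param reps Number of random splits (default 1000).
#' @param error "mape" (mean absolute percentage error, default) or
#'   "rmse_pct" (100 RMSE / mean of held-out truth).
#' @param seed Optional integer seed for reproducible splits.
#' @return Object of class `proxy_ensemble`.
#' @export
cv_ensemble <- function(data, response,
                        predictors = c("peak_c_star", "peak_t_star",
                                       "theta_c"),
                        train_fraction = 0.8, reps = 1000,
                        error = c("mape", "rmse_pct"), seed = NULL) {
  error <- match.arg(error)
  stopifnot(train_fraction > 0, train_fraction < 1, reps >= 1,
            nrow(data) >= 10)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  n_train <- floor(train_fraction * n)
  terms <- c("(Intercept)", predictors)
  coefs <- matrix(NA_real_, reps, length(terms),
                  dimnames = list(NULL, terms))
  errs <- numeric(reps)
  redraws <- 0L
  fml <- stats::reformulate(predictors, response)
  for (r in seq_len(reps)) {
    repeat {
      tr <- sample.int(n, n_train)
      Xtr <- as.matrix(data[tr, predictors])
      if (qr(cbind(1, Xtr))$rank == length(terms)) break
      redraws <- redraws + 1L
    }
    fit <- stats::lm(fml, data = data[tr, ])
    coefs[r, ] <- stats::coef(fit)[terms]
    held <- data[-tr, ]
    pred <- stats::predict(fit, newdata = held)
    truth <- held[[response]]
    errs[r] <- if (error == "mape") {
      100 * mean(abs(pred - truth) / abs(truth))
    } else {
      100 * sqrt(mean((pred - truth)^2)) / mean(truth)
    }
  }
  structure(list(response = response,
                 predictors = predictors,
                 coef_mean = colMeans(coefs),
                 coef_sd = apply(coefs, 2, stats::sd),
                 coefs = coefs,
                 mean_error_pct = mean(errs),
                 error_type = error,
                 n_reps = reps,
                 train_fraction = train_fraction,
                 n = n,
                 n_redraws = redraws,
                 seed = seed),
            class = "proxy_ensemble")
}

#' @export
print.proxy_ensemble <- function(x, ...) {
  cat(sprintf(
    "<proxy_ensemble> %s, %d reps of %.0f%%/%.0f%% splits (n = %d)\n",
    x$response, x$n_reps, 100 * x$train_fraction,
    100 * (1 - x$train_fraction), x$n))
  print(round(rbind(mean = x$coef_mean, sd = x$coef_sd), 4))
  cat(sprintf("  mean held-out error: %.2f%% (%s)\n",
              x$mean_error_pct, x$error_type))
  invisible(x)
}

#' Tidy a cross-validation ensemble
#' @param x A `proxy_ensemble`.
#' @param ... Unused.
#' @return Tibble with term, estimate (ensemble mean), std.error (ensemble
#'   SD).
#' @exportS3Method generics::tidy
tidy.proxy_ensemble <- function(x, ...) {
  tibble::tibble(term = names(x$coef_mean),
                 estimate = unname(x$coef_mean),
                 std.error = unname(x$coef_sd))
}

#' Glance at a cross-validation ensemble
#' @param x A `proxy_ensemble`.
#' @param ... Unused.
#' @return One-row tibble with mean error, reps and split size.
#' @exportS3Method generics::glance
glance.proxy_ensemble <- function(x, ...) {
  tibble::tibble(mean.error.pct = x$mean_error_pct,
                 error.type = x$error_type,
                 n.reps = x$n_reps,
                 train.fraction = x$train_fraction,
                 nobs = x$n)
}

#' Predict molecular indices from optical measurements
#'
#' Applies the ensemble mean coefficients to new optical data; an optional
#' first-order prediction standard error is propagated from the ensemble
#' coefficient SDs (independence approximation).
#'
#' @param ensembles A single `proxy_ensemble` or a named list of them (one
#'   per index).
#' @param newdata Tibble holding the predictor columns.
#' @param se Logical: append propagated prediction SE columns?
#' @return `newdata` with one predicted column per ensemble (named
#'   `pred_<response>`), plus `pred_<response>_se` when `se = TRUE`.
#' @export
predict_indices <- function(ensembles, newdata, se = FALSE) {
  if (inherits(ensembles, "proxy_ensemble")) {
    ensembles <- stats::setNames(list(ensembles), ensembles$response)
  }
  out <- tibble::as_tibble(newdata)
  for (ens in ensembles) {
    missing <- setdiff(ens$predictors, names(newdata))
    if (length(missing)) {
      stop(sprintf("missing predictor column(s): %s",
                   paste(missing, collapse = ", ")))
    }
    X <- cbind(1, as.matrix(newdata[ens$predictors]))
    out[[paste0("pred_", ens$response)]] <-
      as.numeric(X %*% ens$coef_mean)
    if (se) {
      out[[paste0("pred_", ens$response, "_se")]] <-
        sqrt(as.numeric(X^2 %*% ens$coef_sd^2))
    }
  }
  out
}

#' Intercalibrate two fluorometers
#'
#' OLS of the reference-instrument measurement on the second instrument's,
#' over paired samples; the returned mapping converts second-instrument
#' readings to the reference scale.
#'
#' @param data Data frame with the paired measurements.
#' @param reference,other Column names of the reference and
#'   second-instrument measurements.
#' @return Object of class `intercalibration`: slope, intercept,
#'   r_squared, p_value, n, and `convert(x)`.
#' @export
intercalibrate <- function(data, reference, other) {
  stopifnot(all(c(reference, other) %in% names(data)))
  x <- data[[other]]
  y <- data[[reference]]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  stopifnot(length(x) >= 5)
  if (stats::sd(x) == 0) stop("second-instrument values are constant")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  structure(list(slope = slope, intercept = intercept,
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(x),
                 reference = reference, other = other,
                 convert = function(v) intercept + slope * v),
            class = "intercalibration")
}

#' @export
print.intercalibration <- function(x, ...) {
  cat(sprintf(
    "<intercalibration> %s = %.4f + %.4f x %s (R2 = %.3f, p = %.3g, n = %d)\n",
    x$reference, x$intercept, x$slope, x$other, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Compare measured and modeled indices
#'
#' Per index: OLS of modeled on measured values with R-squared, p-value
#' and the number of points diverging more than 3 residual standard
#' deviations from the regression line.
#'
#' @param data Data frame with paired columns.
#' @param pairs Named character vector: names are measured columns, values
#'   the corresponding modeled columns.
#' @return List with `summary` (one row per index) and `points` (long
#'   scatter table with residuals and divergence flags), class
#'   `measured_modeled`.
#' @export
compare_measured_modeled <- function(data, pairs) {
  stopifnot(length(pairs) >= 1, !is.null(names(pairs)))
  rows <- list(); pts <- list()
  for (i in seq_along(pairs)) {
    measured <- names(pairs)[i]
    modeled <- pairs[[i]]
    x <- data[[measured]]; y <- data[[modeled]]
    ok <- stats::complete.cases(x, y)
    fit <- stats::lm(y[ok] ~ x[ok])
    sm <- summary(fit)
    res <- stats::residuals(fit)
    sd_res <- stats::sd(res)
    eps <- 1e-10 * (max(abs(y[ok])) + 1)
    divergent <- if (sd_res > eps) abs(res) > 3 * sd_res else
      rep(FALSE, length(res))
    rows[[i]] <- tibble::tibble(
      index = measured,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = sm$r.squared,
      p_value = if (nrow(sm$coefficients) > 1)
        sm$coefficients[2, 4] else NA_real_,
      n = sum(ok),
      n_divergent = sum(divergent))
    pts[[i]] <- tibble::tibble(index = measured,
                               measured = x[ok], modeled = y[ok],
                               residual = res, divergent = divergent)
  }
  structure(list(summary = dplyr::bind_rows(rows),
                 points = dplyr::bind_rows(pts)),
            class = "measured_modeled")
}

#' @export
print.measured_modeled <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Scatter plot of measured versus modeled indices
#'
#' @param object A `measured_modeled` result.
#' @param ... Unused.
#' @return A ggplot facetted by index, with the 1:1 line.
#' @exportS3Method ggplot2::autoplot
autoplot.measured_modeled <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$measured, y = .data$modeled)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$divergent),
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(~index, scales = "free") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "measured", y = "modeled")
}
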