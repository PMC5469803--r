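# Proxy regressions, cross-validation ensembles, prediction and
# intercalibration.

make_linear_data <- function(n = 29, sigma = 0, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    peak_c_star = runif(n, 0.5, 2),
    peak_t_star = runif(n, 3, 12),
    theta_c = runif(n, 13, 20)
  ) |>
    dplyr::mutate(y = 7.89 + 0.32 * peak_c_star - 0.02 * peak_t_star -
                    0.02 * theta_c + rnorm(n, 0, sigma))
}

test_that("noiseless fits recover coefficients exactly", {
  d <- make_linear_data(sigma = 0)
  f <- suppressWarnings(fit_proxy_model(d, "y"))  # perfect fit warns
  expect_equal(unname(f$coefficients),
               c(7.89, 0.32, -0.02, -0.02), tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_equal(f$see_pct, 0, tolerance = 1e-8)
  # constant response: zero slopes, intercept equals the constant
  d2 <- dplyr::mutate(d, y = 5)
  f2 <- suppressWarnings(fit_proxy_model(d2, "y"))
  expect_equal(unname(f2$coefficients), c(5, 0, 0, 0), tolerance = 1e-10)
})

test_that("fit agrees with a hand-solved normal-equations oracle", {
  d <- tibble::tibble(x1 = c(1, 2, 3, 4, 5), x2 = c(2, 1, 4, 3, 6),
                      y = c(3.1, 3.9, 6.2, 6.8, 9.5))
  f <- fit_proxy_model(d, "y", predictors = c("x1", "x2"))
  X <- cbind(1, d$x1, d$x2)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(unname(f$coefficients), as.numeric(beta_oracle),
               tolerance = 1e-10)
  # residual orthogonality to every predictor column
  res <- d$y - X %*% beta_oracle
  expect_lt(max(abs(t(X) %*% res)) / max(abs(d$y)), 1e-8)
})

test_that("rank-deficient designs fail naming the collinear column", {
  d <- make_linear_data()
  d$dup <- 2 * d$peak_c_star
  expect_error(fit_proxy_model(d, "y",
                               predictors = c("peak_c_star", "dup")),
               "collinear")
})

test_that("standardised betas follow the sd ratio definition", {
  d <- make_linear_data(sigma = 0.05, seed = 3)
  f <- fit_proxy_model(d, "y")
  expect_equal(unname(f$beta["peak_c_star"]),
               unname(f$coefficients["peak_c_star"]) *
                 sd(d$peak_c_star) / sd(d$y))
})

test_that("cross-validation ensembles are deterministic and collapse on noiseless data", {
  d <- make_linear_data(sigma = 0)
  e1 <- cv_ensemble(d, "y", reps = 50, seed = 11)
  expect_equal(unname(e1$coef_sd), rep(0, 4), tolerance = 1e-9)
  expect_equal(e1$mean_error_pct, 0, tolerance = 1e-8)
  e2 <- cv_ensemble(d, "y", reps = 50, seed = 11)
  expect_identical(e1$coefs, e2$coefs)
  # split sizes: floor(0.8 * 29) = 23 train / 6 test
  expect_equal(floor(0.8 * nrow(d)), 23)
})

test_that("ensemble means converge to the full fit for large reps and fractions", {
  d <- make_linear_data(sigma = 0.2, seed = 5)
  full <- fit_proxy_model(d, "y")
  e <- cv_ensemble(d, "y", train_fraction = 0.95, reps = 4000, seed = 2)
  expect_equal(unname(e$coef_mean), unname(full$coefficients),
               tolerance = 0.05)
})

test_that("prediction applies ensemble coefficients", {
  d <- make_linear_data(sigma = 0)
  e <- cv_ensemble(d, "y", reps = 20, seed = 1)
  pred <- predict_indices(e, d)
  expect_equal(pred$pred_y, d$y, tolerance = 1e-8)
  # all predictors zero -> intercept
  zero <- tibble::tibble(peak_c_star = 0, peak_t_star = 0, theta_c = 0)
  expect_equal(predict_indices(e, zero)$pred_y,
               unname(e$coef_mean["(Intercept)"]), tolerance = 1e-8)
  expect_error(predict_indices(e, zero[, 1:2]), "missing predictor")
  # hand-computed worked case for the UA-style model at (1, 10, 13)
  ens <- structure(list(response = "ua",
                        predictors = c("peak_c_star", "peak_t_star",
                                       "theta_c"),
                        coef_mean = c(`(Intercept)` = 5.5,
                                      peak_c_star = -2.5,
                                      peak_t_star = 0.23, theta_c = 0.39),
                        coef_sd = rep(0, 4)),
                   class = "proxy_ensemble")
  nd <- tibble::tibble(peak_c_star = 1, peak_t_star = 10, theta_c = 13)
  expect_equal(predict_indices(ens, nd)$pred_ua, 10.37, tolerance = 1e-10)
})

test_that("intercalibration recovers linear instrument maps", {
  d <- tibble::tibble(other = seq(1, 5, length.out = 29))
  d$ref <- d$other
  cal <- suppressWarnings(intercalibrate(d, "ref", "other"))
  expect_equal(cal$slope, 1, tolerance = 1e-10)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  expect_equal(cal$r_squared, 1)
  d$ref <- 2 * d$other + 1
  cal2 <- suppressWarnings(intercalibrate(d, "ref", "other"))
  expect_equal(cal2$slope, 2, tolerance = 1e-10)
  expect_equal(cal2$convert(3), 7, tolerance = 1e-10)
  set.seed(6)
  d$ref <- 2 * d$other + 1 + rnorm(29, 0, 0.1)
  cal3 <- intercalibrate(d, "ref", "other")
  expect_gt(cal3$slope, 1.9); expect_lt(cal3$slope, 2.1)
  d$flat <- 1
  expect_error(intercalibrate(d, "ref", "flat"), "constant")
})

test_that("measured-vs-modeled comparison finds identity and noise", {
  d <- tibble::tibble(m = rnorm(30, 10), mod = NA_real_)
  d$mod <- d$m
  cmp <- suppressWarnings(compare_measured_modeled(d, c(m = "mod")))
  expect_equal(cmp$summary$r_squared, 1)
  expect_equal(cmp$summary$n_divergent, 0)
  set.seed(9)
  d$mod <- rnorm(30)
  cmp2 <- compare_measured_modeled(d, c(m = "mod"))
  expect_lt(cmp2$summary$r_squared, 0.2)
})

test_that("tidy and glance methods expose fit summaries", {
  d <- make_linear_data(sigma = 0.1, seed = 8)
  f <- fit_proxy_model(d, "y")
  td <- tidy(f)
  expect_setequal(td$term, c("(Intercept)", "peak_c_star", "peak_t_star",
                             "theta_c"))
  expect_true(all(c("estimate", "std.error", "beta") %in% names(td)))
  gl <- glance(f)
  expect_equal(gl$nobs, 29)
  e <- cv_ensemble(d, "y", reps = 30, seed = 4)
  expect_equal(nrow(tidy(e)), 4)
  expect_true("mean.error.pct" %in% names(glance(e)))
})
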