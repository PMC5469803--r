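# Synthetic transect generator: latent state, optics, targets, library,
# spectra, EEMs and reproducibility.

test_that("degradation latent saturates monotonically with depth", {
  expect_equal(latent_profile(0), 0)
  expect_equal(latent_profile(500, scale_m = 500), 1 - exp(-1))
  expect_gt(latent_profile(1e6), 1 - 1e-9)
  expect_error(latent_profile(-5), "non-negative")
  d <- latent_profile(seq(0, 3000, by = 100))
  expect_true(all(diff(d) > 0))
})

test_that("optical truths are monotone in the latent and deterministic at zero noise", {
  lat <- tibble::tibble(d = c(0, 1), doc_umol = c(60, 42))
  o1 <- generate_optics(lat, noise_scale = 0)
  expect_lt(o1$peak_c_star[1], o1$peak_c_star[2])
  expect_gt(o1$peak_t_star[1], o1$peak_t_star[2])
  expect_true(all(o1$hix > 0))
  o2 <- generate_optics(lat, noise_scale = 0)
  expect_identical(o1, o2)
  expect_error(generate_optics(tibble::tibble(d = 2, doc_umol = 50)),
               "d must")
  expect_error(generate_optics(tibble::tibble(d = 0.5, doc_umol = 0)),
               "DOC")
})

test_that("index values stay inside the study ranges over many draws", {
  set.seed(123)
  lat <- tibble::tibble(d = runif(1e4), doc_umol = runif(1e4, 42, 60))
  o <- generate_optics(lat)
  expect_true(all(o$hix >= 0.5 & o$hix <= 10))
  expect_true(all(o$fi > 1.7 & o$fi < 2.3))
  expect_true(all(o$peak_c_star > 0))
})

test_that("index targets follow the generative linear model", {
  co <- default_index_coefficients()
  opt <- tibble::tibble(peak_c_star = 0, peak_t_star = 0, theta_c = 0)
  tg <- target_indices(opt, co, noise_scale = 0)
  expect_equal(tg$dbe, 7.89)          # DBE intercept
  expect_equal(tg$ideg, 0.75)
  # hand-computed Ideg row at (1, 1, 13)
  opt2 <- tibble::tibble(peak_c_star = 1, peak_t_star = 1, theta_c = 13)
  tg2 <- target_indices(opt2, co, noise_scale = 0)
  expect_equal(tg2$ideg, 0.13 - 0.016 - 0.0015 * 13 + 0.75)
  expect_equal(tg2$ideg, 0.8445)
  # all-zero coefficients reduce to the intercept for any input
  co0 <- dplyr::mutate(co, b_c = 0, b_t = 0, b_theta = 0, intercept = 4.2)
  tg3 <- target_indices(opt2, co0, noise_scale = 0)
  expect_true(all(unlist(tg3[co$index]) == 4.2))
})

test_that("formula library honours class targets, markers and the DBE gap", {
  set.seed(2)
  lib <- build_formula_library(1500)
  expect_gte(nrow(lib), 1500)
  # every entry passes the validity rules of the formula module
  expect_true(all(is_valid_formula(lib$c, lib$h, lib$n, lib$o, lib$s,
                                   lib$p,
                                   rules = formula_rules(
                                     mass_range = c(154, 817)))))
  expect_true(all(lib$exact_mass >= 154 & lib$exact_mass <= 817))
  # both end-members are normalised distributions
  expect_equal(sum(lib$w_fresh), 1)
  expect_equal(sum(lib$w_degraded), 1)
  expect_true(all(lib$w_fresh >= 0 & lib$w_degraded >= 0))
  # degraded end-member strictly more unsaturated
  expect_gt(library_dbe(lib, 1) - library_dbe(lib, 0), 1)
  # markers always included
  mk <- ideg_markers()
  lib_str <- formula_string(lib$c, lib$h, lib$n, lib$o, lib$s, lib$p)
  expect_true(all(mk$formula %in% lib_str))
  # empty request and infeasible targets fail loudly
  expect_equal(nrow(build_formula_library(0)), 0)
  expect_error(generate_spectrum(build_formula_library(0), 7),
               "empty")
  expect_error(build_formula_library(
    5e4, class_targets = c(unsaturated_aliphatic = 0.9)), "infeasible")
})

test_that("same seed reproduces the library exactly", {
  set.seed(42); l1 <- build_formula_library(500)
  set.seed(42); l2 <- build_formula_library(500)
  expect_identical(l1, l2)
})

test_that("spectrum generation solves the mixing fraction to 1e-6", {
  set.seed(4)
  lib <- build_formula_library(800)
  lo <- library_dbe(lib, 0); hi <- library_dbe(lib, 1)
  # end-members map to f = 0 and f = 1
  expect_equal(attr(generate_spectrum(lib, lo, noise_cv = 0), "f"), 0,
               tolerance = 1e-6)
  expect_equal(attr(generate_spectrum(lib, hi, noise_cv = 0), "f"), 1,
               tolerance = 1e-6)
  # any feasible target closes the loop through the formula module
  for (target in c(lo + 0.3, (lo + hi) / 2, hi - 0.2)) {
    sp <- generate_spectrum(lib, target, noise_cv = 0)
    a <- assign_formulas(sp)
    expect_equal(weighted_index(a, "dbe"), target, tolerance = 1e-6)
  }
  expect_error(generate_spectrum(lib, hi + 1), "attainable range")
})

test_that("generated EEMs superimpose scatter that removal excises", {
  tg <- c(A = 0, C = 0, M = 0, T = 0, B = 0)
  e0 <- generate_eem(tg, noise_sd = 0, scatter = FALSE)
  expect_true(all(e0$intensity == 0))
  # with zero amplitudes the matrix is zero away from the ridges
  e1 <- generate_eem(c(A = 1, C = 1, M = 1, T = 1, B = 1), noise_sd = 0,
                     scatter = TRUE)
  i <- which(e1$excitation == 320)
  on_ridge <- which.min(abs(e1$emission - 320))
  off <- remove_scatter(e1)
  expect_gt(e1$intensity[i, on_ridge], off$intensity[i, on_ridge])
  expect_true(off$mask[i, on_ridge])
})

test_that("simulated transects are reproducible and internally consistent", {
  cfg <- fast_config(seed = 9)
  t1 <- simulate_transect(cfg)
  t2 <- simulate_transect(cfg)
  expect_identical(t1$truth, t2$truth)
  expect_identical(t1$peaks, t2$peaks)
  t3 <- simulate_transect(fast_config(seed = 10))
  expect_false(identical(t1$truth$peak_c_star, t3$truth$peak_c_star))
  # sample table structure
  expect_equal(sum(!t1$samples$optics_only), cfg$n_full)
  expect_equal(sum(t1$samples$optics_only), cfg$n_optics_only)
  expect_true(all(t1$samples$doc_umol > cfg$doc_deep - 1e-9 &
                    t1$samples$doc_umol <= cfg$doc_surface))
  # one EEM, spectrum and peak list per full sample
  full_ids <- t1$samples$sample_id[!t1$samples$optics_only]
  expect_setequal(names(t1$eems), full_ids)
  expect_setequal(names(t1$peaks), full_ids)
})

test_that("config invariants are enforced", {
  expect_error(transect_config(depths_per_station = c(100, 50)))
  expect_error(transect_config(doc_surface = 40, doc_deep = 42))
  expect_error(transect_config(n_stations = 0))
})
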