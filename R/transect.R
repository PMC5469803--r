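# Synthetic trans-basin transect generator: water samples with a depth-driven
# degradation gradient, optical truths, EEMs, absorbance spectra and FT-ICR-MS
# style peak lists with controlled optical-molecular covariance.

#' Default generative coefficients of the molecular-index proxy models
#'
#' Linear coefficients linking each intensity-weighted molecular index
#' (DBE, degradation index, unsaturated-aliphatic %, CRAM %) to peak C*,
#' peak T* (NFIU L / mg C) and potential temperature (deg C), together with
#' their ensemble standard deviations, percent standard error of estimate
#' and R-squared. These serve as the generator's ground truth; `noise_sd`
#' is the residual standard deviation calibrated so that the residual
#' equals `see_pct` percent of a typical index mean.
#'
#' @return Tibble with one row per index.
#' @export
default_index_coefficients <- function() {
  tibble::tibble(
    index = c("dbe", "ideg", "ua", "cram"),
    b_c = c(0.32, 0.13, -2.5, 1.8),
    b_t = c(-0.02, -0.016, 0.23, -0.24),
    b_theta = c(-0.02, -0.0015, 0.39, -0.21),
    intercept = c(7.89, 0.75, 5.5, 54.2),
    sd_c = c(0.12, 0.03, 0.9, 0.7),
    sd_t = c(0.01, 0.003, 0.07, 0.05),
    sd_theta = c(0.02, 0.006, 0.18, 0.15),
    sd_intercept = c(0.47, 0.11, 3.4, 2.7),
    see_pct = c(1.0, 4.6, 6.7, 1.1),
    r2 = c(0.73, 0.85, 0.80, 0.65),
    noise_sd = c(0.08, 0.035, 0.65, 0.57)
  )
}

#' Transect generator configuration
#'
#' @param n_stations Number of stations with full (optics + molecular)
#'   characterisation.
#' @param depths_per_station Strictly positive, sorted sampling depths (m).
#' @param n_full Total number of fully characterised samples (the station x
#'   depth grid is truncated or extended with extra shallow casts to reach
#'   it).
#' @param n_optics_only Number of optics-only samples measured on a second
#'   fluorometer.
#' @param doc_surface,doc_deep Surface and deep DOC (umol C / L);
#'   `doc_surface` must exceed `doc_deep`.
#' @param doc_scale_m E-folding depth (m) of the DOC decay.
#' @param latent_scale_m E-folding depth (m) of the degradation latent.
#' @param theta_dcm,theta_deep Potential temperature (deg C) at the deep
#'   chlorophyll maximum and at depth for a station without basin offset.
#' @param theta_station_range Range (deg C) of the west-to-east basin
#'   warming added per station.
#' @param coefficients Generative coefficient table
#'   ([default_index_coefficients()]).
#' @param noise_scale Multiplier on every stochastic component (0 =
#'   deterministic generator).
#' @param peak_noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise on mass-peak intensities (replicate-spectrum
#'   reproducibility; default 0.13).
#' @param n_formulas Formula library size.
#' @param em_step Emission sampling step (nm) of generated EEMs.
#' @param seed Integer seed.
#' @return A list of class `transect_config`.
#' @export
transect_config <- function(n_stations = 7,
                            depths_per_station = c(75, 500, 1000, 2500),
                            n_full = 29,
                            n_optics_only = 400,
                            doc_surface = 60, doc_deep = 42,
                            doc_scale_m = 300,
                            latent_scale_m = 500,
                            theta_dcm = 14.5, theta_deep = 13.0,
                            theta_station_range = 9,
                            coefficients = default_index_coefficients(),
                            noise_scale = 1,
                            peak_noise_cv = 0.13,
                            n_formulas = 2500,
                            em_step = 1,
                            seed = 1L) {
  stopifnot(n_stations >= 1,
            all(depths_per_station > 0),
            !is.unsorted(depths_per_station, strictly = TRUE),
            doc_surface > doc_deep,
            noise_scale >= 0, peak_noise_cv >= 0,
            n_full >= 1)
  structure(list(n_stations = n_stations,
                 depths_per_station = depths_per_station,
                 n_full = n_full, n_optics_only = n_optics_only,
                 doc_surface = doc_surface, doc_deep = doc_deep,
                 doc_scale_m = doc_scale_m,
                 latent_scale_m = latent_scale_m,
                 theta_dcm = theta_dcm, theta_deep = theta_deep,
                 theta_station_range = theta_station_range,
                 coefficients = coefficients,
                 noise_scale = noise_scale,
                 peak_noise_cv = peak_noise_cv,
                 n_formulas = n_formulas,
                 em_step = em_step,
                 seed = as.integer(seed)),
            class = "transect_config")
}

#' Degradation latent state of a depth
#'
#' Saturating monotone map of depth onto the [0, 1] degradation scalar:
#' d = 1 - exp(-depth / scale). Deterministic.
#'
#' @param depth_m Depth in metres (>= 0, vectorised).
#' @param scale_m E-folding depth (default 500 m).
#' @return Numeric vector in [0, 1).
#' @export
latent_profile <- function(depth_m, scale_m = 500) {
  if (any(depth_m < 0)) stop("depth must be non-negative")
  1 - exp(-depth_m / scale_m)
}

# DOC depth profile: exponential decay towards the deep value
doc_profile <- function(depth_m, doc_surface = 60, doc_deep = 42,
                        scale_m = 300) {
  doc_deep + (doc_surface - doc_deep) * exp(-depth_m / scale_m)
}

# mean-preserving multiplicative lognormal factor with sdlog s
lognoise <- function(n, s) {
  if (s <= 0) return(rep(1, n))
  exp(stats::rnorm(n, -s^2 / 2, s))
}

#' Generate scalar optical truths from the latent state
#'
#' Peak C* increases affinely with the degradation latent while peak T*,
#' a254* and the freshness-type indices decrease; HIX increases.
#' Mean-preserving multiplicative lognormal variability represents both
#' measurement noise and the real decoupling of fluorophore pools from the
#' mean depth trend; all outputs are positive.
#'
#' @param latent Tibble with columns `d` (degradation scalar in [0, 1]) and
#'   `doc_umol` (> 0).
#' @param noise_scale Multiplier on the lognormal sdlog values (0 =
#'   deterministic).
#' @return `latent` with columns `peak_c_star`, `peak_t_star`, `fi`, `fri`,
#'   `bix`, `hix`, `a254_star` appended (starred units: NFIU L / mg C and
#'   L / m / mg C).
#' @export
generate_optics <- function(latent, noise_scale = 1) {
  stopifnot(is.data.frame(latent),
            all(c("d", "doc_umol") %in% names(latent)))
  if (any(latent$d < 0 | latent$d > 1)) stop("d must lie in [0, 1]")
  if (any(latent$doc_umol <= 0)) stop("DOC must be positive")
  d <- latent$d
  n <- length(d)
  s <- function(x) x * noise_scale
  dplyr::mutate(tibble::as_tibble(latent),
    peak_c_star = (0.6 + 1.2 * d) * lognoise(n, s(0.30)),
    peak_t_star = (10 - 5 * d) * lognoise(n, s(0.60)),
    fi = (2.12 - 0.22 * d) * lognoise(n, s(0.015)),
    fri = (0.96 - 0.12 * d) * lognoise(n, s(0.02)),
    bix = (0.95 - 0.12 * d) * lognoise(n, s(0.02)),
    hix = (1.3 + 4.8 * d) * lognoise(n, s(0.08)),
    a254_star = (2.6 - 1.2 * d) * lognoise(n, s(0.10))
  )
}

#' Generate molecular-index targets from optical truths
#'
#' Each index is the linear model intercept + b_C peakC* + b_T peakT* +
#' b_theta theta evaluated on the observed optical values, plus Gaussian
#' residual noise of standard deviation `noise_sd` from the coefficient
#' table.
#'
#' @param optics Tibble with columns `peak_c_star`, `peak_t_star`, `theta_c`.
#' @param coefficients Coefficient table ([default_index_coefficients()]).
#' @param noise_scale Multiplier on the residual standard deviations.
#' @return `optics` with one target column per index (`dbe`, `ideg`, `ua`,
#'   `cram` at defaults).
#' @export
target_indices <- function(optics, coefficients = default_index_coefficients(),
                           noise_scale = 1) {
  stopifnot(all(c("peak_c_star", "peak_t_star", "theta_c") %in% names(optics)))
  out <- tibble::as_tibble(optics)
  n <- nrow(out)
  for (i in seq_len(nrow(coefficients))) {
    co <- coefficients[i, ]
    out[[co$index]] <- co$intercept +
      co$b_c * out$peak_c_star + co$b_t * out$peak_t_star +
      co$b_theta * out$theta_c +
      stats::rnorm(n, 0, co$noise_sd * noise_scale)
  }
  out
}

# ---------------------------------------------------------------------------
# Formula library and spectra

#' Build a two-end-member formula library
#'
#' Samples valid CHNOSP formulae stratified by compound class (defaults
#' reflect open-ocean SPE-DOM: highly unsaturated dominant, then
#' unsaturated aliphatics and polyphenols) and attaches two normalised
#' end-member intensity distributions: a "fresh" member tilted towards low
#' DBE and aliphatic/peptide formulae, and a "degraded" member tilted
#' towards high-DBE highly-unsaturated and CRAM formulae. The ten
#' degradation-index marker formulae are always included.
#'
#' @param n Number of formulae (>= 0; downstream stages refuse an empty
#'   library).
#' @param class_targets Named fractions (need not sum to 1; remainder is
#'   drawn from all classes).
#' @param rules Validity rules; the default restricts masses to 154-817 Da.
#' @param markers Degradation-index marker table to force-include.
#' @return Tibble of class `formula_library`: element counts, `exact_mass`,
#'   `dbe`, `class`, `cram`, and normalised `w_fresh`, `w_degraded`.
#' @export
build_formula_library <- function(n = 2500,
                                  class_targets = c(
                                    highly_unsaturated = 0.704,
                                    unsaturated_aliphatic = 0.137,
                                    polyphenols = 0.118,
                                    peptides = 0.025,
                                    saturated_fatty_acids = 0.008,
                                    sugars = 0.006),
                                  rules = formula_rules(mass_range = c(154, 817)),
                                  markers = ideg_markers()) {
  if (n == 0) {
    out <- tibble::tibble(c = integer(), h = integer(), n = integer(),
                          o = integer(), s = integer(), p = integer(),
                          exact_mass = numeric(), dbe = numeric(),
                          class = character(), cram = logical(),
                          w_fresh = numeric(), w_degraded = numeric())
    class(out) <- c("formula_library", class(out))
    return(out)
  }
  universe <- candidate_library(rules)
  universe <- annotate_formulas(universe[c("c", "h", "n", "o", "s", "p")],
                                rules = rules)
  counts <- round(class_targets * n)
  picked <- vector("list", length(counts) + 1L)
  for (i in seq_along(counts)) {
    pool <- which(universe$class == names(counts)[i])
    if (length(pool) < counts[i]) {
      stop(sprintf(
        "class target infeasible: need %d '%s' formulae, universe has %d",
        counts[i], names(counts)[i], length(pool)))
    }
    picked[[i]] <- sample(pool, counts[i])
  }
  rest <- n - sum(counts)
  if (rest > 0) {
    pool <- setdiff(seq_len(nrow(universe)), unlist(picked))
    picked[[length(counts) + 1L]] <- sample(pool, rest)
  }
  lib <- universe[sort(unique(unlist(picked))), ]

  # force-include the degradation-index markers
  mk <- annotate_formulas(parse_formula(markers$formula), rules = rules)
  lib <- dplyr::bind_rows(lib,
                          dplyr::anti_join(mk, lib,
                                           by = c("c", "h", "n", "o", "s", "p")))

  # end-member tilts: fresh favours low DBE + aliphatic classes, degraded
  # favours high DBE + highly-unsaturated / CRAM formulae; the common
  # mass decay keeps intensity-weighted MW near open-ocean values
  base <- exp(-lib$exact_mass / 100)
  fresh_boost <- ifelse(lib$class %in%
                          c("unsaturated_aliphatic", "peptides",
                            "saturated_fatty_acids"), 4, 1)
  degr_boost <- ifelse(lib$class == "highly_unsaturated" | lib$cram, 3, 1)
  w_f <- base * exp(-lib$dbe / 20) * fresh_boost
  w_d <- base * exp(lib$dbe / 45) * degr_boost
  w_f <- w_f / sum(w_f)
  w_d <- w_d / sum(w_d)
  # degradation-index markers are major peaks with strong end-member
  # contrast: the numerator ("neg") set loads on the degraded member, the
  # "pos" set on the fresh member, so the index tracks the mixing state
  lib_str <- formula_string(lib$c, lib$h, lib$n, lib$o, lib$s, lib$p)
  neg_idx <- which(lib_str %in% markers$formula[markers$role == "neg"])
  pos_idx <- which(lib_str %in% markers$formula[markers$role == "pos"])
  w_f[pos_idx] <- 0.012
  w_f[neg_idx] <- 0.0006
  w_d[pos_idx] <- 0.0006
  w_d[neg_idx] <- 0.012
  lib$w_fresh <- w_f / sum(w_f)
  lib$w_degraded <- w_d / sum(w_d)
  lib <- lib[c("c", "h", "n", "o", "s", "p", "exact_mass", "dbe",
               "class", "cram", "w_fresh", "w_degraded")]
  class(lib) <- c("formula_library", class(lib))
  lib
}

#' Intensity-weighted DBE of a library end-member mix
#'
#' @param library A [build_formula_library()] tibble.
#' @param f Mixing fraction in [0, 1] (0 = fresh, 1 = degraded).
#' @return Scalar weighted DBE.
#' @export
library_dbe <- function(library, f) {
  w <- (1 - f) * library$w_fresh + f * library$w_degraded
  sum(w * library$dbe) / sum(w)
}

#' Generate a mass-peak list realising a target weighted DBE
#'
#' The fresh/degraded mixing fraction is solved by bisection so that the
#' intensity-weighted DBE of the mixture matches `target_dbe` to 1e-6;
#' per-peak mean-preserving lognormal noise (replicate-spectrum
#' reproducibility) is then applied. The synthetic S/N scales with
#' relative intensity above a floor, so at defaults every generated peak
#' passes the detection and normalisation filters and the noiseless loop
#' closes exactly.
#'
#' @param library A non-empty [build_formula_library()] tibble.
#' @param target_dbe Target intensity-weighted DBE; must lie within the
#'   library's attainable [fresh, degraded] range.
#' @param noise_cv Coefficient of variation of the peak noise (0 =
#'   deterministic).
#' @param intensity_scale Arbitrary-unit scale of raw intensities.
#' @param sn_floor Minimum synthetic S/N.
#' @return Tibble with `neutral_mass`, `intensity`, `sn` plus the latent
#'   mixing fraction in attribute `f`.
#' @export
generate_spectrum <- function(library, target_dbe, noise_cv = 0.13,
                              intensity_scale = 1e8, sn_floor = 6) {
  if (nrow(library) == 0) stop("empty formula library")
  lo <- library_dbe(library, 0)
  hi <- library_dbe(library, 1)
  rng <- sort(c(lo, hi))
  if (target_dbe < rng[1] - 1e-9 || target_dbe > rng[2] + 1e-9) {
    stop(sprintf(
      "target DBE %.4f outside the attainable range [%.4f, %.4f]",
      target_dbe, rng[1], rng[2]))
  }
  froot <- stats::uniroot(function(f) library_dbe(library, f) - target_dbe,
                          interval = c(0, 1), tol = 1e-12)$root
  w <- (1 - froot) * library$w_fresh + froot * library$w_degraded
  sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  intensity <- w * intensity_scale * lognoise(length(w), sdlog)
  rel <- intensity / max(intensity)
  out <- tibble::tibble(
    neutral_mass = library$exact_mass,
    intensity = intensity,
    sn = sn_floor + rel * 200
  )
  attr(out, "f") <- froot
  out
}

# ---------------------------------------------------------------------------
# EEM and absorbance synthesis

# 2-D Gaussian fluorophore response on an (ex, em) grid
gauss2d <- function(ex, em, ex0, em0, s_ex = 25, s_em = 30) {
  outer(exp(-(ex - ex0)^2 / (2 * s_ex^2)),
        exp(-(em - em0)^2 / (2 * s_em^2)))
}

#' Generate a synthetic EEM realising classical peak targets
#'
#' The EEM is a sum of five 2-D Gaussian fluorophores centred at the
#' classical peak coordinates, with amplitudes solved from a 5 x 5 linear
#' system so that the noiseless, scatter-free surface evaluates exactly to
#' the requested peak intensities at the peak nodes. First- and
#' second-order Rayleigh and water-Raman ridges and additive Gaussian
#' noise can be superimposed.
#'
#' @param peak_targets Named numeric vector with elements A, C, M, T, B
#'   (NFIU).
#' @param em_step Emission step (nm); excitation is fixed at 240-450 nm in
#'   10 nm steps (22 scans), emission spans 300-560 nm.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param scatter Logical: superimpose scatter ridges?
#' @param scatter_amp Ridge amplitude relative to the largest peak target.
#' @param s_ex,s_em Gaussian fluorophore widths (nm).
#' @return An [eem()] object.
#' @export
generate_eem <- function(peak_targets, em_step = 1, noise_sd = 0,
                         scatter = TRUE, scatter_amp = 5,
                         s_ex = 25, s_em = 30) {
  stopifnot(all(c("A", "C", "M", "T", "B") %in% names(peak_targets)))
  ex <- seq(240, 450, by = 10)
  em <- seq(300, 560, by = em_step)
  pc <- peak_coordinates()
  targets <- peak_targets[pc$peak]
  # response matrix: row i = contributions of each fluorophore at peak i
  M <- outer(seq_len(5), seq_len(5), Vectorize(function(i, j) {
    exp(-(pc$ex[i] - pc$ex[j])^2 / (2 * s_ex^2)) *
      exp(-(pc$em[i] - pc$em[j])^2 / (2 * s_em^2))
  }))
  amps <- solve(M, as.numeric(targets))
  z <- matrix(0, length(ex), length(em))
  for (j in seq_len(5)) {
    z <- z + amps[j] * gauss2d(ex, em, pc$ex[j], pc$em[j], s_ex, s_em)
  }
  if (scatter) {
    ridge_amp <- scatter_amp * max(abs(as.numeric(targets)), 1e-12)
    for (i in seq_along(ex)) {
      z[i, ] <- z[i, ] +
        ridge_amp * exp(-(em - ex[i])^2 / (2 * 4^2)) +
        0.3 * ridge_amp * exp(-(em - 2 * ex[i])^2 / (2 * 6^2)) +
        0.1 * ridge_amp * exp(-(em - raman_emission(ex[i]))^2 / (2 * 2^2))
    }
  }
  if (noise_sd > 0) {
    z <- z + matrix(stats::rnorm(length(z), 0, noise_sd),
                    nrow(z), ncol(z))
  }
  eem(ex, em, z)
}

#' Generate a CDOM absorbance spectrum with a target a254
#'
#' Exponential CDOM shape A(lambda) = A254 exp(-S (lambda - 254)) in
#' decadal absorbance, with A254 back-calculated from the requested
#' Napierian coefficient and pathlength.
#'
#' @param a254 Target Napierian absorption coefficient at 254 nm (1/m).
#' @param pathlength_m Cuvette pathlength (m).
#' @param slope Spectral slope (1/nm, default 0.018).
#' @param wavelengths Wavelength grid (nm).
#' @return Tibble with `wavelength_nm` and `absorbance`.
#' @export
generate_absorbance <- function(a254, pathlength_m = 0.1, slope = 0.018,
                                wavelengths = 250:750) {
  A254 <- a254 * pathlength_m / log(10)
  tibble::tibble(wavelength_nm = as.numeric(wavelengths),
                 absorbance = A254 * exp(-slope * (wavelengths - 254)))
}

# ---------------------------------------------------------------------------
# Full transect

# sample table: station grid for full samples plus optics-only casts
build_sample_table <- function(config) {
  lons <- seq(-5, 32, length.out = config$n_stations)
  grid <- tidyr::expand_grid(station = seq_len(config$n_stations),
                             depth_m = config$depths_per_station)
  # extend with extra shallow casts if the grid is short of n_full
  while (nrow(grid) < config$n_full) {
    extra <- tibble::tibble(station = (nrow(grid) %% config$n_stations) + 1L,
                            depth_m = 200)
    grid <- dplyr::bind_rows(grid, extra)
  }
  grid <- grid[seq_len(config$n_full), ]
  full <- grid |>
    dplyr::mutate(sample_id = sprintf("S%02d_%04.0fm", .data$station,
                                      .data$depth_m),
                  longitude = lons[.data$station],
                  optics_only = FALSE)
  oo <- tibble::tibble(
    sample_id = sprintf("O%03d", seq_len(config$n_optics_only)),
    station = sample.int(config$n_stations, config$n_optics_only,
                         replace = TRUE),
    depth_m = stats::runif(config$n_optics_only, 50, 3000),
    optics_only = TRUE
  ) |>
    dplyr::mutate(longitude = lons[.data$station])
  dplyr::bind_rows(full, oo)
}

#' Simulate a full synthetic transect
#'
#' Generates the sample table (station, depth, potential temperature,
#' salinity, DOC), the latent degradation state, scalar optical truths,
#' molecular-index targets, EEMs and absorbance spectra for the fully
#' characterised samples, FT-ICR-MS style peak lists anchored on the DBE
#' target, and second-instrument peak measurements for every sample (the
#' optics-only casts are measured on that instrument alone).
#'
#' @param config A [transect_config()].
#' @return A list of class `dom_transect` with elements `config`, `samples`,
#'   `truth` (per-sample latents, optical truths and index targets),
#'   `library`, `eems`, `spectra`, `peaks`, `instrument_b` (per-sample
#'   second-fluorometer peak C / peak T readings).
#' @export
simulate_transect <- function(config = transect_config()) {
  stopifnot(inherits(config, "transect_config"))
  set.seed(config$seed)
  ns <- config$noise_scale

  samples <- build_sample_table(config)
  station_offset <- stats::runif(config$n_stations, 0,
                                 config$theta_station_range)
  d <- latent_profile(samples$depth_m, config$latent_scale_m)
  samples <- samples |>
    dplyr::mutate(
      d = d,
      theta_c = config$theta_deep +
        (config$theta_dcm - config$theta_deep) * (1 - .data$d) +
        station_offset[.data$station],
      salinity = 36.5 + 0.06 * .data$longitude + 0.1 * .data$d,
      doc_umol = doc_profile(.data$depth_m, config$doc_surface,
                             config$doc_deep, config$doc_scale_m)
    )

  truth <- generate_optics(samples, noise_scale = ns) |>
    target_indices(config$coefficients, noise_scale = ns)

  library <- build_formula_library(n = config$n_formulas)
  dbe_rng <- sort(c(library_dbe(library, 0), library_dbe(library, 1)))

  full <- truth |> dplyr::filter(!.data$optics_only)
  doc_mg <- full$doc_umol * 12.011e-3

  # unstarred NFIU peak targets; A, M, B tied to C and T with small
  # independent variability
  n_full <- nrow(full)
  peak_c <- full$peak_c_star * doc_mg
  peak_t <- full$peak_t_star * doc_mg
  peak_a <- 1.9 * peak_c * lognoise(n_full, 0.05 * ns)
  peak_m <- 0.8 * peak_c * lognoise(n_full, 0.05 * ns)
  peak_b <- 0.5 * peak_t * lognoise(n_full, 0.05 * ns)

  eems <- vector("list", n_full)
  spectra <- vector("list", n_full)
  peaks <- vector("list", n_full)
  fs <- numeric(n_full)
  for (i in seq_len(n_full)) {
    tg <- c(A = peak_a[i], C = peak_c[i], M = peak_m[i],
            T = peak_t[i], B = peak_b[i])
    eems[[i]] <- generate_eem(tg, em_step = config$em_step,
                              noise_sd = ns * 0.002 * max(tg))
    spectra[[i]] <- generate_absorbance(full$a254_star[i] * doc_mg[i])
    target <- min(max(full$dbe[i], dbe_rng[1]), dbe_rng[2])
    sp <- generate_spectrum(library, target,
                            noise_cv = ns * config$peak_noise_cv)
    fs[i] <- attr(sp, "f")
    peaks[[i]] <- sp
  }
  names(eems) <- names(spectra) <- names(peaks) <- full$sample_id
  truth$f <- NA_real_
  truth$f[match(full$sample_id, truth$sample_id)] <- fs

  # second fluorometer: linear instrument response + noise, all samples
  instrument_b <- truth |>
    dplyr::transmute(
      .data$sample_id,
      peak_c_b = (1.3 * .data$peak_c_star * .data$doc_umol * 12.011e-3 +
                    0.05) * lognoise(dplyr::n(), 0.06 * ns),
      peak_t_b = (1.25 * .data$peak_t_star * .data$doc_umol * 12.011e-3 +
                    0.1) * lognoise(dplyr::n(), 0.09 * ns)
    )

  structure(list(config = config,
                 samples = samples,
                 truth = truth,
                 library = library,
                 eems = eems,
                 spectra = spectra,
                 peaks = peaks,
                 instrument_b = instrument_b),
            class = "dom_transect")
}

#' @export
print.dom_transect <- function(x, ...) {
  cat(sprintf(
    "<dom_transect> %d full + %d optics-only samples, %d stations, %d formulae\n",
    sum(!x$samples$optics_only), sum(x$samples$optics_only),
    x$config$n_stations, nrow(x$library)))
  invisible(x)
}
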