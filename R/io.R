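# Plain-text readers/writers for every pipeline artefact, plus the
# end-to-end pipeline driver.

#' Write an EEM grid to CSV
#'
#' Layout: first column `ex_nm` (excitation), remaining column names are
#' the emission wavelengths in nm.
#'
#' @param x An [eem()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_eem_csv <- function(x, path) {
  stopifnot(inherits(x, "eem"))
  df <- data.frame(ex_nm = x$excitation, x$intensity, check.names = FALSE)
  names(df)[-1] <- as.character(x$emission)
  readr::write_csv(df, path)
  invisible(path)
}

#' Read an EEM grid from CSV
#'
#' @param path File written by [write_eem_csv()].
#' @return An [eem()].
#' @export
read_eem_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "ex_nm") stop("EEM CSV must start with an ex_nm column")
  ex <- df$ex_nm
  em <- as.numeric(names(df)[-1])
  if (anyNA(em)) stop("EEM CSV header must hold numeric emission wavelengths")
  if (any(diff(ex) <= 0) || any(diff(em) <= 0)) {
    stop("EEM wavelength vectors must be strictly increasing")
  }
  eem(ex, em, as.matrix(df[-1]))
}

#' Write / read an absorbance spectrum CSV
#'
#' Two columns: `wavelength_nm`, `absorbance` (decadal).
#'
#' @param spectrum Tibble with those columns.
#' @param path File path.
#' @return `path` (write) or the tibble (read).
#' @export
write_absorbance_csv <- function(spectrum, path) {
  stopifnot(all(c("wavelength_nm", "absorbance") %in% names(spectrum)))
  readr::write_csv(spectrum[c("wavelength_nm", "absorbance")], path)
  invisible(path)
}

#' @rdname write_absorbance_csv
#' @export
read_absorbance_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("wavelength_nm", "absorbance") %in% names(df))) {
    stop("absorbance CSV needs wavelength_nm and absorbance columns")
  }
  if (is.unsorted(df$wavelength_nm, strictly = TRUE)) {
    stop("absorbance wavelengths must be strictly increasing")
  }
  if (any(df$absorbance < 0)) stop("negative absorbance values")
  tibble::as_tibble(df)
}

#' Write / read a mass-peak list TSV
#'
#' Columns `neutral_mass_da`, `intensity`, `sn`.
#'
#' @param peaks Tibble with columns `neutral_mass`, `intensity`, `sn`.
#' @param path File path.
#' @return `path` (write) or a tibble with `neutral_mass`, `intensity`,
#'   `sn` (read).
#' @export
write_peaks_tsv <- function(peaks, path) {
  stopifnot(all(c("neutral_mass", "intensity", "sn") %in% names(peaks)))
  out <- tibble::tibble(neutral_mass_da = peaks$neutral_mass,
                        intensity = peaks$intensity, sn = peaks$sn)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_peaks_tsv
#' @export
read_peaks_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("neutral_mass_da", "intensity", "sn")
  if (!all(need %in% names(raw))) {
    stop("peak TSV needs neutral_mass_da, intensity and sn columns")
  }
  for (col in need) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' at data line %d of %s",
                   col, bad[1], path))
    }
    raw[[col]] <- v
  }
  tibble::tibble(neutral_mass = raw$neutral_mass_da,
                 intensity = raw$intensity, sn = raw$sn)
}

#' Write / read the sample metadata CSV
#'
#' @param samples Sample tibble (must have unique `sample_id`).
#' @param path File path.
#' @return `path` (write) or the tibble (read).
#' @export
write_samples_csv <- function(samples, path) {
  stopifnot("sample_id" %in% names(samples))
  readr::write_csv(samples, path)
  invisible(path)
}

#' @rdname write_samples_csv
#' @export
read_samples_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(df)) stop("samples CSV needs a sample_id column")
  if (anyDuplicated(df$sample_id)) {
    stop(sprintf("duplicate sample id: %s",
                 df$sample_id[duplicated(df$sample_id)][1]))
  }
  tibble::as_tibble(df)
}

#' Write a simulated transect to a directory
#'
#' Emits samples.csv, eem_<id>.csv, abs_<id>.csv and peaks_<id>.tsv for
#' the fully characterised samples, instrument_b.csv for all samples, and
#' truth.json with the latent states and generative parameters.
#'
#' @param transect A [simulate_transect()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_transect <- function(transect, dir) {
  stopifnot(inherits(transect, "dom_transect"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_samples_csv(transect$samples, file.path(dir, "samples.csv"))
  readr::write_csv(transect$instrument_b, file.path(dir, "instrument_b.csv"))
  for (id in names(transect$eems)) {
    write_eem_csv(transect$eems[[id]],
                  file.path(dir, sprintf("eem_%s.csv", id)))
    write_absorbance_csv(transect$spectra[[id]],
                         file.path(dir, sprintf("abs_%s.csv", id)))
    write_peaks_tsv(transect$peaks[[id]],
                    file.path(dir, sprintf("peaks_%s.tsv", id)))
  }
  truth <- list(seed = transect$config$seed,
                noise_scale = transect$config$noise_scale,
                coefficients = transect$config$coefficients,
                samples = transect$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# ---------------------------------------------------------------------------
# End-to-end pipeline

#' Run the full analysis pipeline on a synthetic transect
#'
#' Chains the stages: simulate, optics extraction (scatter removal, peak
#' picking, indices), formula assignment, molecular indices, Spearman
#' screening, cross-validated proxy regressions, instrument
#' intercalibration and prediction of the optics-only samples, and the
#' measured-versus-modeled comparison. The returned manifest records the
#' seed and content hashes of every stage output, so identical
#' (config, seed) pairs give identical manifests.
#'
#' @param config A [transect_config()].
#' @param reps Cross-validation repetitions (default 1000).
#' @param screen_min_present Minimum-presence filter for screening.
#' @return A list of class `dom_pipeline` with elements `transect`,
#'   `optical` (recovered optical indices), `assigned`, `molecular`,
#'   `joined`, `screen`, `ensembles`, `intercalibration`, `predicted`,
#'   `comparison`, `manifest`.
#' @export
run_transect_pipeline <- function(config = transect_config(), reps = 1000,
                                  screen_min_present = 3) {
  transect <- simulate_transect(config)
  full <- transect$samples |> dplyr::filter(!.data$optics_only)

  # optics stage: scatter removal + parameter extraction
  eems <- purrr::map(transect$eems, remove_scatter)
  optical <- optical_indices(full, eems, transect$spectra)

  # assignment stage
  assigned <- purrr::imap(transect$peaks, function(p, id) {
    dplyr::mutate(assign_formulas(p), sample_id = id)
  }) |>
    dplyr::bind_rows()
  molecular <- molecular_indices(assigned)

  joined <- optical |>
    dplyr::inner_join(molecular, by = "sample_id")

  screen <- screen_formulae(assigned, optical,
                            min_present = screen_min_present)

  responses <- c(dbe = "dbe_w", ideg = "ideg",
                 ua = "pct_unsaturated_aliphatic", cram = "pct_cram")
  ensembles <- purrr::map(responses, function(col) {
    cv_ensemble(joined, col, reps = reps)
  })

  # intercalibration on the dual-measured samples, then predict the
  # optics-only casts on the reference scale
  ib <- transect$instrument_b
  cal_data <- optical |>
    dplyr::inner_join(ib, by = "sample_id")
  cal_c <- intercalibrate(cal_data, "peak_c", "peak_c_b")
  cal_t <- intercalibrate(cal_data, "peak_t", "peak_t_b")

  oo <- transect$samples |>
    dplyr::filter(.data$optics_only) |>
    dplyr::inner_join(ib, by = "sample_id") |>
    dplyr::mutate(
      peak_c_star = carbon_specific(cal_c$convert(.data$peak_c_b),
                                    .data$doc_umol),
      peak_t_star = carbon_specific(cal_t$convert(.data$peak_t_b),
                                    .data$doc_umol))
  predicted <- predict_indices(ensembles, oo)

  modeled29 <- predict_indices(ensembles, joined)
  pairs <- stats::setNames(paste0("pred_", unname(responses)),
                           unname(responses))
  comparison <- compare_measured_modeled(modeled29, pairs)

  manifest <- list(
    seed = config$seed,
    n_full = nrow(full),
    n_optics_only = sum(transect$samples$optics_only),
    n_formulae_library = nrow(transect$library),
    hashes = list(samples = rlang::hash(transect$samples),
                  optical = rlang::hash(optical),
                  molecular = rlang::hash(molecular),
                  flags = rlang::hash(screen$flags),
                  ensembles = rlang::hash(purrr::map(ensembles,
                                                     `[`, c("coef_mean",
                                                            "coef_sd"))),
                  predicted = rlang::hash(predicted))
  )

  structure(list(transect = transect, optical = optical,
                 assigned = assigned, molecular = molecular,
                 joined = joined, screen = screen, ensembles = ensembles,
                 intercalibration = list(peak_c = cal_c, peak_t = cal_t),
                 predicted = predicted, comparison = comparison,
                 manifest = manifest),
            class = "dom_pipeline")
}

#' @export
print.dom_pipeline <- function(x, ...) {
  cat(sprintf(
    "<dom_pipeline> seed %d: %d full samples, %d optics-only, %d screened formulae\n",
    x$manifest$seed, x$manifest$n_full, x$manifest$n_optics_only,
    x$screen$n_formulae))
  invisible(x)
}
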