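# Excitation-emission matrices, absorbance spectra and the derived optical
# parameter set (classical peaks, carbon-specific quantities, ratios and the
# FI / FrI / BIX / HIX fluorescence indices).

#' Construct an excitation-emission matrix
#'
#' @param excitation Strictly increasing excitation wavelengths (nm).
#' @param emission Strictly increasing emission wavelengths (nm).
#' @param intensity Numeric matrix, `length(excitation)` rows by
#'   `length(emission)` columns (NFIU or raw counts).
#' @param mask Optional logical matrix of the same shape marking excised
#'   scatter cells (TRUE = masked).
#' @return An object of class `eem`.
#' @export
eem <- function(excitation, emission, intensity, mask = NULL) {
  stopifnot(is.numeric(excitation), is.numeric(emission),
            is.matrix(intensity))
  if (any(diff(excitation) <= 0) || any(diff(emission) <= 0)) {
    stop("wavelength vectors must be strictly increasing")
  }
  if (nrow(intensity) != length(excitation) ||
      ncol(intensity) != length(emission)) {
    stop("intensity matrix dimensions must match the wavelength vectors")
  }
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(intensity), ncol(intensity))
  }
  stopifnot(identical(dim(mask), dim(intensity)))
  if (any(!is.finite(intensity[!mask]))) {
    stop("intensities must be finite outside the mask")
  }
  structure(list(excitation = excitation, emission = emission,
                 intensity = intensity, mask = mask),
            class = "eem")
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf("<eem> %d excitation x %d emission (%g-%g / %g-%g nm), %d masked cells\n",
              length(x$excitation), length(x$emission),
              min(x$excitation), max(x$excitation),
              min(x$emission), max(x$emission), sum(x$mask)))
  invisible(x)
}

#' EEM as a long tibble
#'
#' @param x An [eem()] object.
#' @return Tibble with columns `excitation`, `emission`, `intensity`,
#'   `masked`.
#' @export
eem_to_tibble <- function(x) {
  stopifnot(inherits(x, "eem"))
  tibble::tibble(
    excitation = rep(x$excitation, times = length(x$emission)),
    emission = rep(x$emission, each = length(x$excitation)),
    intensity = as.vector(x$intensity),
    masked = as.vector(x$mask)
  )
}

#' Blank-subtract and scale an EEM to NFIU
#'
#' output = (sample - blank) * standard_factor elementwise, where the
#' factor is set by quinine sulfate / tryptophan standards.
#'
#' @param eem_raw Sample [eem()].
#' @param blank_eem Blank [eem()] on the identical grid.
#' @param standard_factor Positive scaling factor to NFIU.
#' @return Normalised [eem()].
#' @export
normalize_to_nfiu <- function(eem_raw, blank_eem, standard_factor = 1) {
  stopifnot(inherits(eem_raw, "eem"), inherits(blank_eem, "eem"),
            standard_factor > 0)
  if (!isTRUE(all.equal(eem_raw$excitation, blank_eem$excitation)) ||
      !isTRUE(all.equal(eem_raw$emission, blank_eem$emission))) {
    stop("sample and blank EEM grids do not match")
  }
  eem(eem_raw$excitation, eem_raw$emission,
      (eem_raw$intensity - blank_eem$intensity) * standard_factor,
      mask = eem_raw$mask | blank_eem$mask)
}

# Raman emission wavelength (nm) of the water OH-stretch band for an
# excitation line, from the 3400 cm^-1 wavenumber shift.
raman_emission <- function(ex_nm, shift_cm = 3400) {
  1 / (1 / ex_nm - shift_cm * 1e-7)
}

#' Remove Rayleigh and Raman scatter ridges from an EEM
#'
#' Cells within the first-order (em ~ ex) and second-order (em ~ 2 ex)
#' Rayleigh ridges and the water Raman ridge (3400 cm-1 shift of the
#' excitation line) are masked and replaced by linear interpolation along
#' the emission axis of each excitation scan. Cells outside the ridges are
#' unchanged, so the operation is idempotent. A scan fully covered by
#' ridges is left masked with a warning.
#'
#' @param x An [eem()].
#' @param first_width Half-width (nm) of the first-order Rayleigh ridge.
#' @param second_width Half-width (nm) of the second-order ridge.
#' @param raman_width Half-width (nm) of the Raman ridge; 0 disables it.
#' @param raman_shift_cm Raman shift in wavenumbers (default 3400).
#' @return An [eem()] with ridge cells interpolated and flagged in `mask`.
#' @export
remove_scatter <- function(x, first_width = 15, second_width = 20,
                           raman_width = 5, raman_shift_cm = 3400) {
  stopifnot(inherits(x, "eem"))
  em <- x$emission
  z <- x$intensity
  mask <- matrix(FALSE, nrow(z), ncol(z))
  for (i in seq_along(x$excitation)) {
    ex <- x$excitation[i]
    bad <- abs(em - ex) <= first_width |
      abs(em - 2 * ex) <= second_width
    if (raman_width > 0) {
      bad <- bad | abs(em - raman_emission(ex, raman_shift_cm)) <= raman_width
    }
    if (all(bad)) {
      warning(sprintf(
        "scatter ridges cover the whole emission scan at excitation %g nm",
        ex))
      mask[i, ] <- TRUE
      z[i, ] <- NA_real_
      next
    }
    if (any(bad)) {
      z[i, bad] <- stats::approx(em[!bad], z[i, !bad], xout = em[bad],
                                 rule = 2)$y
      mask[i, bad] <- TRUE
    }
  }
  eem(x$excitation, x$emission, z, mask = mask)
}

# index of the grid node nearest to w, ties towards the lower wavelength
nearest_node <- function(grid, w) {
  d <- abs(grid - w)
  which(d == min(d))[1]
}

#' Read a fluorescence peak off an EEM
#'
#' Intensity at the grid node nearest to the requested excitation/emission
#' pair (ties towards the lower wavelength). Optionally averages over a
#' symmetric emission window around the nominal pair.
#'
#' @param x An [eem()].
#' @param ex_nm,em_nm Requested coordinates, which must lie inside the grid
#'   hull.
#' @param em_window Emission half-window (nm) for averaging; 0 (default)
#'   reads the single nearest node.
#' @return Scalar intensity.
#' @export
pick_peak <- function(x, ex_nm, em_nm, em_window = 0) {
  stopifnot(inherits(x, "eem"))
  if (ex_nm < min(x$excitation) || ex_nm > max(x$excitation) ||
      em_nm < min(x$emission) || em_nm > max(x$emission)) {
    stop(sprintf("requested coordinates (%g, %g) outside the EEM grid hull",
                 ex_nm, em_nm))
  }
  i <- nearest_node(x$excitation, ex_nm)
  if (em_window > 0) {
    sel <- abs(x$emission - em_nm) <= em_window
    return(mean(x$intensity[i, sel]))
  }
  j <- nearest_node(x$emission, em_nm)
  x$intensity[i, j]
}

#' Classical fluorescence peak coordinates
#'
#' Excitation/emission pairs of peaks A (general humic-like), C
#' (terrestrial humic-like), M (marine humic-like), T (tryptophan-like) and
#' B (tyrosine-like).
#'
#' @return Tibble with columns `peak`, `ex`, `em`.
#' @export
peak_coordinates <- function() {
  tibble::tibble(
    peak = c("A", "C", "M", "T", "B"),
    ex = c(250, 340, 320, 280, 270),
    em = c(435, 440, 410, 350, 304)
  )
}

# emission scan at the excitation node nearest ex_nm
emission_scan <- function(x, ex_nm) {
  i <- nearest_node(x$excitation, ex_nm)
  list(em = x$emission, intensity = x$intensity[i, ])
}

# trapezoid integral of scan over [lo, hi] on the native grid
band_integral <- function(scan, lo, hi) {
  sel <- scan$em >= lo & scan$em <= hi
  if (sum(sel) < 2) return(NA_real_)
  em <- scan$em[sel]
  y <- scan$intensity[sel]
  sum(diff(em) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Fluorescence indices FI, FrI, BIX and HIX
#'
#' FI = I(370, 470) / I(370, 520); FrI = I(310, 380) / max I(310, em) over
#' em in [420, 435]; BIX = I(310, 380) / I(310, 430); HIX = integral of the
#' emission scan at excitation 260 nm over [435, 480] divided by the
#' integral over [300, 345], both by trapezoid on the native grid
#' (non-normalised humification ratio). Zero denominators yield NA with a
#' warning rather than infinities.
#'
#' @param x An [eem()] whose emission axis covers 300-520 nm at excitations
#'   260, 310 and 370 nm.
#' @return One-row tibble with columns `fi`, `fri`, `bix`, `hix`.
#' @export
fluorescence_indices <- function(x) {
  stopifnot(inherits(x, "eem"))
  safe_ratio <- function(num, den, what) {
    if (!is.finite(den) || den == 0) {
      warning(sprintf("%s denominator is zero or missing; index undefined",
                      what))
      return(NA_real_)
    }
    num / den
  }
  fi <- safe_ratio(pick_peak(x, 370, 470), pick_peak(x, 370, 520), "FI")
  s310 <- emission_scan(x, 310)
  fr_den <- max(s310$intensity[s310$em >= 420 & s310$em <= 435])
  fri <- safe_ratio(pick_peak(x, 310, 380), fr_den, "FrI")
  bix <- safe_ratio(pick_peak(x, 310, 380), pick_peak(x, 310, 430), "BIX")
  s260 <- emission_scan(x, 260)
  hix <- safe_ratio(band_integral(s260, 435, 480),
                    band_integral(s260, 300, 345), "HIX")
  tibble::tibble(fi = fi, fri = fri, bix = bix, hix = hix)
}

#' Decadal absorbance to Napierian absorption coefficient
#'
#' a(lambda) = ln(10) * A(lambda) / pathlength, in 1/m.
#'
#' @param spectrum Data frame with columns `wavelength_nm` and `absorbance`
#'   (dimensionless decadal absorbance).
#' @param pathlength_m Cuvette pathlength in metres (> 0).
#' @return Tibble with `wavelength_nm` and `a_m` (1/m).
#' @export
absorbance_to_napierian <- function(spectrum, pathlength_m = 0.1) {
  stopifnot(is.data.frame(spectrum),
            all(c("wavelength_nm", "absorbance") %in% names(spectrum)),
            pathlength_m > 0)
  tibble::tibble(wavelength_nm = spectrum$wavelength_nm,
                 a_m = log(10) * spectrum$absorbance / pathlength_m)
}

#' Carbon-specific normalisation
#'
#' Divides a fluorescence intensity or absorption coefficient by the DOC
#' concentration expressed in mg C per litre (1 umol C = 12.011e-3 mg C),
#' giving e.g. NFIU L / mg C.
#'
#' @param value Quantity to normalise (vectorised).
#' @param doc_umol DOC concentration in umol C per litre (> 0).
#' @return value / DOC(mg C / L).
#' @export
carbon_specific <- function(value, doc_umol) {
  if (any(doc_umol <= 0)) stop("DOC concentration must be positive")
  value / (doc_umol * 12.011e-3)
}

#' Full optical parameter set for one sample
#'
#' Picks the five classical peaks, forms carbon-specific (starred)
#' intensities, the a254 absorption coefficient and its carbon-specific
#' version, the A/T, C/T, M/T and C/M ratios, and the four fluorescence
#' indices.
#'
#' @param x Scatter-corrected [eem()] in NFIU.
#' @param spectrum Absorbance spectrum data frame (see
#'   [absorbance_to_napierian()]); may be NULL to skip a254.
#' @param doc_umol DOC concentration, umol C per litre.
#' @param pathlength_m Absorbance pathlength in metres.
#' @param em_window Emission averaging half-window passed to [pick_peak()].
#' @return One-row tibble with peaks, starred peaks, `a254`, `a254_star`,
#'   ratios and indices.
#' @export
optical_index_set <- function(x, spectrum = NULL, doc_umol,
                              pathlength_m = 0.1, em_window = 0) {
  pc <- peak_coordinates()
  vals <- purrr::map2_dbl(pc$ex, pc$em,
                          ~ pick_peak(x, .x, .y, em_window = em_window))
  names(vals) <- tolower(pc$peak)
  a254 <- NA_real_
  if (!is.null(spectrum)) {
    nap <- absorbance_to_napierian(spectrum, pathlength_m)
    j <- nearest_node(nap$wavelength_nm, 254)
    a254 <- nap$a_m[j]
  }
  idx <- fluorescence_indices(x)
  tibble::tibble(
    peak_a = vals[["a"]], peak_c = vals[["c"]], peak_m = vals[["m"]],
    peak_t = vals[["t"]], peak_b = vals[["b"]],
    peak_a_star = carbon_specific(vals[["a"]], doc_umol),
    peak_c_star = carbon_specific(vals[["c"]], doc_umol),
    peak_m_star = carbon_specific(vals[["m"]], doc_umol),
    peak_t_star = carbon_specific(vals[["t"]], doc_umol),
    a254 = a254,
    a254_star = if (is.na(a254)) NA_real_ else
      carbon_specific(a254, doc_umol),
    ratio_a_t = vals[["a"]] / vals[["t"]],
    ratio_c_t = vals[["c"]] / vals[["t"]],
    ratio_m_t = vals[["m"]] / vals[["t"]],
    ratio_c_m = vals[["c"]] / vals[["m"]],
    fi = idx$fi, fri = idx$fri, bix = idx$bix, hix = idx$hix
  )
}

#' Optical indices for a set of samples
#'
#' @param samples Tibble with at least `sample_id` and `doc_umol` columns.
#' @param eems Named list of scatter-corrected [eem()] objects keyed by
#'   sample id.
#' @param spectra Optional named list of absorbance spectra keyed by sample
#'   id.
#' @param ... Passed to [optical_index_set()].
#' @return `samples` joined with one row of optical parameters per sample.
#' @export
optical_indices <- function(samples, eems, spectra = NULL, ...) {
  stopifnot(all(c("sample_id", "doc_umol") %in% names(samples)))
  rows <- purrr::pmap(list(samples$sample_id, samples$doc_umol),
                      function(id, doc) {
    if (!id %in% names(eems)) stop(sprintf("no EEM for sample '%s'", id))
    optical_index_set(eems[[id]],
                      spectrum = if (!is.null(spectra)) spectra[[id]],
                      doc_umol = doc, ...)
  })
  dplyr::bind_cols(tibble::as_tibble(samples), dplyr::bind_rows(rows))
}
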