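# Molecular formula arithmetic, validity rules, compound classification and
# per-sample intensity-weighted indices for FT-ICR-MS peak lists.

#' Monoisotopic element masses (Da)
#'
#' Exact masses of the isotopes used for neutral monoisotopic mass
#' calculation of CHNOSP formulae.
#'
#' @format Named numeric vector with elements C, H, N, O, S, P.
#' @export
element_masses <- c(
  C = 12.000000,
  H = 1.00782503,
  N = 14.00307401,
  O = 15.99491462,
  S = 31.97207069,
  P = 30.97376151
)

# mass of a proton, used to convert [M-H]- m/z to neutral mass
PROTON_MASS <- 1.00727646

#' Exact neutral monoisotopic mass of a formula
#'
#' @param c,h,n,o,s,p Element counts (vectorised, non-negative integers).
#' @return Numeric vector of neutral monoisotopic masses in Da.
#' @examples
#' formula_mass(6, 10, o = 5) # levoglucosan-type C6H10O5
#' @export
formula_mass <- function(c, h, n = 0, o = 0, s = 0, p = 0) {
  c * element_masses[["C"]] + h * element_masses[["H"]] +
    n * element_masses[["N"]] + o * element_masses[["O"]] +
    s * element_masses[["S"]] + p * element_masses[["P"]]
}

#' Double bond equivalents
#'
#' DBE = 1 + C - H/2 + N/2 + P/2. Oxygen and sulfur are divalent and do not
#' enter the count.
#'
#' @inheritParams formula_mass
#' @return Numeric vector of DBE values (may be fractional for invalid
#'   parity; validity rules reject non-integer DBE).
#' @export
dbe <- function(c, h, n = 0, p = 0) {
  1 + c - h / 2 + n / 2 + p / 2
}

#' Modified aromaticity index
#'
#' AImod = (1 + C - O/2 - S - H/2) / (C - O/2 - N - S - P), with half the
#' oxygen treated as carbonyl-like. Set to 0 when the denominator is
#' non-positive or the numerator negative, so the index is always defined.
#'
#' @inheritParams formula_mass
#' @return Numeric vector in [0, Inf), typically [0, 1].
#' @export
aimod <- function(c, h, n = 0, o = 0, s = 0, p = 0) {
  num <- 1 + c - o / 2 - s - h / 2
  den <- c - o / 2 - n - s - p
  out <- ifelse(den > 0 & num >= 0, num / den, 0)
  # guard: all-zero formula
  out[c == 0] <- 0
  out
}

#' Validity rules for formula assignment
#'
#' Bounds and ratio windows a candidate CHNOSP composition must satisfy.
#' Defaults follow common practice for marine solid-phase-extracted DOM:
#' H/C in [0.3, 2.5], O/C in [0, 1.2], up to 4 N, 2 S, 1 P, and an integer
#' non-negative DBE (valence parity).
#'
#' @param h_c,o_c Length-2 numeric windows for the H/C and O/C ratios.
#' @param c_max,h_max,n_max,o_max,s_max,p_max Upper element-count bounds.
#' @param mass_range Length-2 window (Da) of assignable neutral masses.
#' @return A list of class `formula_rules`.
#' @export
formula_rules <- function(h_c = c(0.3, 2.5), o_c = c(0, 1.2),
                          c_max = 60, h_max = 122, n_max = 4,
                          o_max = 40, s_max = 2, p_max = 1,
                          mass_range = c(100, 850)) {
  stopifnot(length(h_c) == 2, length(o_c) == 2, length(mass_range) == 2,
            mass_range[1] < mass_range[2])
  structure(list(h_c = h_c, o_c = o_c, c_max = c_max, h_max = h_max,
                 n_max = n_max, o_max = o_max, s_max = s_max, p_max = p_max,
                 mass_range = mass_range),
            class = "formula_rules")
}

#' Test compositions against the validity rules
#'
#' @inheritParams formula_mass
#' @param rules A [formula_rules()] object.
#' @return Logical vector: TRUE where the composition passes every rule.
#' @export
is_valid_formula <- function(c, h, n = 0, o = 0, s = 0, p = 0,
                             rules = formula_rules()) {
  d <- dbe(c, h, n = n, p = p)
  hc <- h / c
  oc <- o / c
  c >= 1 & h >= 1 &
    c <= rules$c_max & h <= rules$h_max &
    n >= 0 & n <= rules$n_max &
    o >= 0 & o <= rules$o_max &
    s >= 0 & s <= rules$s_max &
    p >= 0 & p <= rules$p_max &
    hc >= rules$h_c[1] & hc <= rules$h_c[2] &
    oc >= rules$o_c[1] & oc <= rules$o_c[2] &
    d >= 0 & abs(d - round(d)) < 1e-9
}

#' Carboxyl-rich alicyclic molecule (CRAM) flag
#'
#' TRUE when DBE/C, DBE/H and DBE/O fall simultaneously inside the windows
#' [0.30, 0.68], [0.20, 0.95] and [0.77, 1.75]. Formulae without oxygen are
#' never CRAM (the DBE/O ratio is undefined).
#'
#' @inheritParams formula_mass
#' @return Logical vector.
#' @export
is_cram <- function(c, h, n = 0, o = 0, p = 0) {
  d <- dbe(c, h, n = n, p = p)
  ok_o <- o >= 1
  rc <- d / c
  rh <- d / h
  ro <- ifelse(ok_o, d / o, NA_real_)
  ok_o &
    rc >= 0.30 & rc <= 0.68 &
    rh >= 0.20 & rh <= 0.95 &
    !is.na(ro) & ro >= 0.77 & ro <= 1.75
}

#' Compound-class labels
#'
#' Assigns each composition to exactly one class by the first matching rule,
#' evaluated in order: sugars (O/C > 0.9); black carbon (AImod > 0.66);
#' polyphenols (0.50 < AImod <= 0.66); highly unsaturated (AImod <= 0.50 and
#' H/C < 1.5); peptides (1.5 <= H/C <= 2.0 with N); unsaturated aliphatic
#' (1.5 <= H/C <= 2.0 without N); saturated fatty acids (H/C > 2.0);
#' anything left is "other". Sugars are tested first so that high-O/C
#' aromatics cannot shadow them.
#'
#' @inheritParams formula_mass
#' @return Character vector of class labels.
#' @export
classify_formula <- function(c, h, n = 0, o = 0, s = 0, p = 0) {
  ai <- aimod(c, h, n = n, o = o, s = s, p = p)
  hc <- h / c
  oc <- o / c
  cls <- rep("other", length(c))
  # reverse order of priority: later assignments overwrite earlier ones,
  # so evaluate from lowest to highest priority
  cls[hc > 2.0] <- "saturated_fatty_acids"
  cls[hc >= 1.5 & hc <= 2.0 & n == 0] <- "unsaturated_aliphatic"
  cls[hc >= 1.5 & hc <= 2.0 & n > 0] <- "peptides"
  cls[ai <= 0.50 & hc < 1.5] <- "highly_unsaturated"
  cls[ai > 0.50 & ai <= 0.66] <- "polyphenols"
  cls[ai > 0.66] <- "black_carbon"
  cls[oc > 0.9] <- "sugars"
  cls
}

#' All compound-class labels in rule order
#' @return Character vector of the eight class labels.
#' @export
compound_classes <- function() {
  c("sugars", "black_carbon", "polyphenols", "highly_unsaturated",
    "peptides", "unsaturated_aliphatic", "saturated_fatty_acids", "other")
}

#' Annotate a table of compositions
#'
#' Adds exact mass, H/C, O/C, DBE, AImod, validity, compound class and CRAM
#' flag columns to a data frame holding element-count columns c, h, n, o, s, p
#' (missing heteroatom columns are treated as zero).
#'
#' @param formulas Data frame with integer columns `c`, `h` and optionally
#'   `n`, `o`, `s`, `p`.
#' @param rules A [formula_rules()] object.
#' @return A tibble with the input columns plus `exact_mass`, `hc`, `oc`,
#'   `dbe`, `aimod`, `valid`, `class`, `cram`.
#' @export
annotate_formulas <- function(formulas, rules = formula_rules()) {
  stopifnot(is.data.frame(formulas), all(c("c", "h") %in% names(formulas)))
  f <- tibble::as_tibble(formulas)
  for (el in c("n", "o", "s", "p")) {
    if (!el %in% names(f)) f[[el]] <- 0L
  }
  f |>
    dplyr::mutate(
      exact_mass = formula_mass(.data$c, .data$h, .data$n, .data$o,
                                .data$s, .data$p),
      hc = .data$h / .data$c,
      oc = .data$o / .data$c,
      dbe = dbe(.data$c, .data$h, n = .data$n, p = .data$p),
      aimod = aimod(.data$c, .data$h, .data$n, .data$o, .data$s, .data$p),
      valid = is_valid_formula(.data$c, .data$h, .data$n, .data$o,
                               .data$s, .data$p, rules = rules),
      class = classify_formula(.data$c, .data$h, .data$n, .data$o,
                               .data$s, .data$p),
      cram = is_cram(.data$c, .data$h, n = .data$n, o = .data$o, p = .data$p)
    )
}

#' Molecular formula string in Hill order
#'
#' @inheritParams formula_mass
#' @return Character vector, e.g. "C6H10O5".
#' @export
formula_string <- function(c, h, n = 0, o = 0, s = 0, p = 0) {
  n <- rep_len(n, length(c)); o <- rep_len(o, length(c))
  s <- rep_len(s, length(c)); p <- rep_len(p, length(c))
  part <- function(sym, cnt) {
    ifelse(cnt == 0, "", ifelse(cnt == 1, sym, paste0(sym, cnt)))
  }
  paste0(part("C", c), part("H", h), part("N", n), part("O", o),
         part("S", s), part("P", p))
}

#' Parse a Hill-order formula string into element counts
#'
#' @param x Character vector like "C16H24O8".
#' @return Tibble with columns c, h, n, o, s, p.
#' @export
parse_formula <- function(x) {
  one <- function(s) {
    m <- gregexpr("([CHNOSP])([0-9]*)", s)[[1]]
    toks <- regmatches(s, gregexpr("([CHNOSP])([0-9]*)", s))[[1]]
    counts <- c(C = 0, H = 0, N = 0, O = 0, S = 0, P = 0)
    for (t in toks) {
      el <- substr(t, 1, 1)
      cnt <- if (nchar(t) > 1) as.integer(substr(t, 2, nchar(t))) else 1L
      counts[el] <- counts[el] + cnt
    }
    counts
  }
  m <- unname(t(vapply(x, one, numeric(6))))
  tibble::tibble(c = m[, 1], h = m[, 2], n = m[, 3],
                 o = m[, 4], s = m[, 5], p = m[, 6])
}

# ---------------------------------------------------------------------------
# Candidate library and assignment

# Enumerate every valid CHNOSP composition inside the rules' bounds and mass
# window. H is stepped with the parity of N + P so DBE stays integral, and
# within the H/C window, which keeps the grid small (~1e6 rows at defaults).
enumerate_valid_formulas <- function(rules = formula_rules()) {
  hetero <- expand.grid(n = 0:rules$n_max, o = 0:rules$o_max,
                        s = 0:rules$s_max, p = 0:rules$p_max)
  base_mass <- with(hetero, formula_mass(0, 0, n, o, s, p))
  keep <- base_mass <= rules$mass_range[2]
  hetero <- hetero[keep, , drop = FALSE]
  base_mass <- base_mass[keep]

  pieces <- vector("list", rules$c_max)
  mC <- element_masses[["C"]]
  mH <- element_masses[["H"]]
  for (cc in seq_len(rules$c_max)) {
    h_lo <- max(1, ceiling(rules$h_c[1] * cc))
    h_hi <- min(rules$h_max, floor(rules$h_c[2] * cc))
    if (h_hi < h_lo) next
    # oxygen bound from O/C window
    o_hi <- floor(rules$o_c[2] * cc)
    sub <- hetero[hetero$o <= o_hi, , drop = FALSE]
    sub_mass <- base_mass[hetero$o <= o_hi]
    # parity of H must match N + P for integer DBE
    par <- (sub$n + sub$p) %% 2
    rows <- vector("list", h_hi - h_lo + 1)
    for (hh in h_lo:h_hi) {
      ok <- par == (hh %% 2)
      # DBE >= 0: h <= 2 + 2c + n + p
      ok <- ok & (hh <= 2 + 2 * cc + sub$n + sub$p)
      if (!any(ok)) next
      mass <- cc * mC + hh * mH + sub_mass[ok]
      inw <- mass >= rules$mass_range[1] & mass <= rules$mass_range[2]
      if (!any(inw)) next
      rows[[hh - h_lo + 1]] <- cbind(c = cc, h = hh,
                                     as.matrix(sub[ok, , drop = FALSE])[inw, ,
                                       drop = FALSE],
                                     exact_mass = mass[inw])
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) pieces[[cc]] <- do.call(rbind, rows)
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  out <- tibble::as_tibble(as.data.frame(do.call(rbind, pieces)))
  out <- out[order(out$exact_mass), ]
  out
}

# cache: the enumerated library for a given rule set (keyed by rule hash)
.formula_cache <- new.env(parent = emptyenv())

candidate_library <- function(rules = formula_rules()) {
  key <- paste(unlist(rules), collapse = "|")
  if (is.null(.formula_cache[[key]])) {
    .formula_cache[[key]] <- enumerate_valid_formulas(rules)
  }
  .formula_cache[[key]]
}

#' Signal-to-noise filter for mass peaks
#'
#' Retains peaks with S/N strictly greater than the threshold. The detection
#' limit uses S/N > 4; the normalisation set uses S/N > 5.
#'
#' @param peaks Data frame with at least an `sn` column.
#' @param threshold S/N cutoff (strict).
#' @return Tibble of retained peaks.
#' @export
sn_filter <- function(peaks, threshold = 4) {
  stopifnot(is.data.frame(peaks), "sn" %in% names(peaks))
  tibble::as_tibble(peaks) |> dplyr::filter(.data$sn > threshold)
}

#' Assign molecular formulae to mass peaks
#'
#' For each peak passing the detection S/N filter, all valid CHNOSP
#' compositions within the relative mass tolerance are enumerated and the
#' candidate with the smallest absolute mass error wins (ties: fewest
#' heteroatoms N+S+P, then lowest N). Unassigned peaks are retained but
#' flagged. Relative intensities of assigned peaks passing the
#' normalisation S/N filter are scaled to sum to one.
#'
#' @param peaks Data frame with columns `neutral_mass` (Da), `intensity`,
#'   `sn`. If `adduct = "mh"`, the mass column is interpreted as [M-H]- m/z
#'   and a proton mass is added back.
#' @param tolerance_ppm Relative mass tolerance (default 0.5 ppm).
#' @param rules A [formula_rules()] object.
#' @param sn_detect Detection S/N threshold (default 4, strict).
#' @param sn_norm Normalisation S/N threshold (default 5, strict).
#' @param adduct "neutral" (default) or "mh" for [M-H]- m/z input.
#' @return A tibble with one row per retained peak: element counts, formula
#'   string, `exact_mass`, `mass_error_ppm`, `rel_intensity` (NA for peaks
#'   outside the normalisation set), `class`, `cram`, `assigned`.
#' @export
assign_formulas <- function(peaks, tolerance_ppm = 0.5,
                            rules = formula_rules(),
                            sn_detect = 4, sn_norm = 5,
                            adduct = c("neutral", "mh")) {
  adduct <- match.arg(adduct)
  stopifnot(is.data.frame(peaks),
            all(c("neutral_mass", "intensity", "sn") %in% names(peaks)),
            tolerance_ppm > 0)
  peaks <- sn_filter(peaks, sn_detect)
  if (nrow(peaks) == 0) {
    warning("no peaks pass the detection S/N filter; empty spectrum")
    return(tibble::tibble(neutral_mass = numeric(), intensity = numeric(),
                          sn = numeric(), c = integer(), h = integer(),
                          n = integer(), o = integer(), s = integer(),
                          p = integer(), formula = character(),
                          exact_mass = numeric(),
                          mass_error_ppm = numeric(),
                          rel_intensity = numeric(), class = character(),
                          cram = logical(), assigned = logical()))
  }
  mass <- peaks$neutral_mass
  if (adduct == "mh") mass <- mass + PROTON_MASS

  lib <- candidate_library(rules)
  lib_mass <- lib$exact_mass

  tol <- mass * tolerance_ppm * 1e-6
  lo <- findInterval(mass - tol, lib_mass) + 1L
  hi <- findInterval(mass + tol, lib_mass)
  lib_het <- lib$n + lib$s + lib$p
  hit <- rep(NA_integer_, length(mass))
  for (k in which(hi >= lo)) {
    idx <- lo[k]:hi[k]
    ord <- order(abs(lib_mass[idx] - mass[k]), lib_het[idx], lib$n[idx])
    hit[k] <- idx[ord[1]]
  }

  out <- tibble::as_tibble(peaks)
  out$neutral_mass <- mass
  assigned <- !is.na(hit)
  sel <- function(col) {
    v <- rep(NA_real_, length(hit))
    v[assigned] <- lib[[col]][hit[assigned]]
    v
  }
  out$c <- sel("c"); out$h <- sel("h"); out$n <- sel("n")
  out$o <- sel("o"); out$s <- sel("s"); out$p <- sel("p")
  out$exact_mass <- sel("exact_mass")
  out$mass_error_ppm <- (out$exact_mass - mass) / mass * 1e6
  out$formula <- NA_character_
  out$formula[assigned] <- formula_string(out$c[assigned], out$h[assigned],
                                          out$n[assigned], out$o[assigned],
                                          out$s[assigned], out$p[assigned])
  out$class <- NA_character_
  out$class[assigned] <- classify_formula(out$c[assigned], out$h[assigned],
                                          out$n[assigned], out$o[assigned],
                                          out$s[assigned], out$p[assigned])
  out$cram <- NA
  out$cram[assigned] <- is_cram(out$c[assigned], out$h[assigned],
                                n = out$n[assigned], o = out$o[assigned],
                                p = out$p[assigned])
  out$assigned <- assigned

  in_norm <- assigned & out$sn > sn_norm
  tot <- sum(out$intensity[in_norm])
  out$rel_intensity <- NA_real_
  if (tot > 0) out$rel_intensity[in_norm] <- out$intensity[in_norm] / tot
  out
}

# ---------------------------------------------------------------------------
# Degradation index and weighted indices

#' Default degradation-index marker formulae
#'
#' The degradation index is an intensity ratio over ten marker formulae:
#' a numerator set of five whose intensity rises as DOM degrades (markers
#' negatively correlated with fresh character, role "neg") and five that
#' fall (role "pos"), so the index increases towards 1 with degradation.
#' The published marker set belongs to the original index reference; the
#' default shipped here is a synthetic stand-in of ten CHO compositions in
#' the 280-440 Da marker mass region, chosen so the numerator set is
#' CRAM-leaning (higher DBE) and the "pos" set aliphatic-leaning. Supply
#' the published set for real-data work.
#'
#' @return Tibble with columns `formula` and `role` ("neg" = numerator,
#'   enriched with degradation; "pos" = depleted with degradation).
#' @export
ideg_markers <- function() {
  tibble::tibble(
    formula = c("C17H20O9", "C17H22O10", "C19H22O10", "C20H22O10",
                "C20H24O11",
                "C13H18O7", "C14H20O7", "C15H22O7", "C15H22O8", "C16H24O8"),
    role = rep(c("neg", "pos"), each = 5)
  )
}

#' Degradation index of a normalised spectrum
#'
#' Ideg = sum I(neg) / (sum I(neg) + sum I(pos)) over the ten marker
#' formulae; increases towards 1 with degradation. Returns NA with a
#' warning when no marker carries intensity.
#'
#' @param spectrum Assigned-spectrum tibble with `formula` and
#'   `rel_intensity` columns (as from [assign_formulas()]).
#' @param markers Marker table as from [ideg_markers()].
#' @return Scalar in [0, 1], or NA if undefined.
#' @export
ideg <- function(spectrum, markers = ideg_markers()) {
  stopifnot(all(c("formula", "rel_intensity") %in% names(spectrum)))
  ii <- spectrum |>
    dplyr::inner_join(markers, by = "formula") |>
    dplyr::group_by(.data$role) |>
    dplyr::summarise(total = sum(.data$rel_intensity, na.rm = TRUE),
                     .groups = "drop")
  s_neg <- sum(ii$total[ii$role == "neg"])
  s_pos <- sum(ii$total[ii$role == "pos"])
  if (s_neg + s_pos <= 0) {
    warning("no degradation-index marker carries intensity; Ideg undefined")
    return(NA_real_)
  }
  s_neg / (s_neg + s_pos)
}

#' Intensity-weighted average of a molecular property
#'
#' @param spectrum Assigned-spectrum tibble with `rel_intensity`.
#' @param property Column to average: one of "exact_mass", "dbe", "hc",
#'   "oc", "aimod" (computed from element counts if absent).
#' @return Weighted mean over rows with non-missing weight; NA if the
#'   spectrum is empty.
#' @export
weighted_index <- function(spectrum, property = c("exact_mass", "dbe", "hc",
                                                  "oc", "aimod")) {
  property <- match.arg(property)
  sp <- spectrum |> dplyr::filter(!is.na(.data$rel_intensity))
  if (nrow(sp) == 0) {
    warning("empty spectrum; weighted index undefined")
    return(NA_real_)
  }
  if (!property %in% names(sp)) {
    sp <- dplyr::mutate(sp,
      dbe = dbe(.data$c, .data$h, n = .data$n, p = .data$p),
      hc = .data$h / .data$c,
      oc = .data$o / .data$c,
      aimod = aimod(.data$c, .data$h, .data$n, .data$o, .data$s, .data$p))
  }
  w <- sp$rel_intensity / sum(sp$rel_intensity)
  sum(w * sp[[property]])
}

#' Per-sample molecular index set
#'
#' Assembles the intensity-weighted molecular weight, DBE, H/C, O/C and
#' AImod, the degradation index, compound-class signal percentages and the
#' CRAM signal percentage of one normalised assigned spectrum.
#'
#' @param spectrum Assigned-spectrum tibble (one sample) from
#'   [assign_formulas()].
#' @param markers Degradation-index marker table.
#' @return One-row tibble: `mw`, `dbe_w`, `hc_w`, `oc_w`, `aimod_w`,
#'   `ideg`, `pct_<class>` for every compound class, `pct_cram`.
#' @export
molecular_index_set <- function(spectrum, markers = ideg_markers()) {
  sp <- spectrum |> dplyr::filter(!is.na(.data$rel_intensity))
  if (nrow(sp) == 0) {
    warning("empty spectrum")
    return(tibble::tibble(mw = NA_real_))
  }
  sp <- sp |> dplyr::mutate(rel_intensity = .data$rel_intensity /
                              sum(.data$rel_intensity))
  cls <- vapply(compound_classes(), function(k) {
    100 * sum(sp$rel_intensity[sp$class == k])
  }, numeric(1))
  names(cls) <- paste0("pct_", names(cls))
  out <- tibble::tibble(
    mw = weighted_index(sp, "exact_mass"),
    dbe_w = weighted_index(sp, "dbe"),
    hc_w = weighted_index(sp, "hc"),
    oc_w = weighted_index(sp, "oc"),
    aimod_w = weighted_index(sp, "aimod"),
    ideg = suppressWarnings(ideg(sp, markers)),
    pct_cram = 100 * sum(sp$rel_intensity[sp$cram])
  )
  dplyr::bind_cols(out, tibble::as_tibble(as.list(cls)))
}

#' Molecular indices for a table of assigned spectra
#'
#' @param assigned Long tibble of assigned peaks for several samples, with a
#'   `sample_id` column (rows as from [assign_formulas()]).
#' @param markers Degradation-index marker table.
#' @return Tibble with one row per sample.
#' @export
molecular_indices <- function(assigned, markers = ideg_markers()) {
  stopifnot("sample_id" %in% names(assigned))
  assigned |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(~ molecular_index_set(.x, markers)) |>
    dplyr::ungroup()
}
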