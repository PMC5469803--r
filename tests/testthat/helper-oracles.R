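# Independent oracles and small fixture builders used across the suite.

# Spearman via explicit mid-ranks + textbook Pearson formula, independent of
# stats::cor(method = "spearman").
brute_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Exhaustive assignment oracle for a neutral mass <= 400 Da: loops the whole
# CHNOSP grid (solving H from the mass within the tolerance window), applies
# the same validity rules and tie-break (|ppm|, then N+S+P, then N), and
# returns the winning formula string or NA.
brute_assign <- function(mass, tolerance_ppm = 0.5,
                         rules = formula_rules()) {
  em <- c(C = 12, H = 1.00782503, N = 14.00307401, O = 15.99491462,
          S = 31.97207069, P = 30.97376151)
  tol <- mass * tolerance_ppm * 1e-6
  best <- NULL
  for (cc in 1:min(rules$c_max, floor(mass / em["C"]))) {
    for (nn in 0:rules$n_max) {
      for (ss in 0:rules$s_max) {
        for (pp in 0:rules$p_max) {
          base <- cc * em["C"] + nn * em["N"] + ss * em["S"] + pp * em["P"]
          if (base > mass + tol) next
          o_max <- min(rules$o_max, floor(rules$o_c[2] * cc),
                       floor((mass + tol - base) / em["O"]))
          for (oo in 0:o_max) {
            rem <- mass - base - oo * em["O"]
            for (hh in unique(c(floor(rem / em["H"]),
                                ceiling(rem / em["H"])))) {
              if (hh < 1) next
              if (!is_valid_formula(cc, hh, nn, oo, ss, pp, rules = rules)) next
              m <- base + oo * em["O"] + hh * em["H"]
              if (m < rules$mass_range[1] || m > rules$mass_range[2]) next
              err <- abs(m - mass)
              if (err > tol) next
              cand <- list(err = err, het = nn + ss + pp, n = nn,
                           formula = formula_string(cc, hh, nn, oo, ss, pp))
              if (is.null(best) ||
                  err < best$err - 1e-15 ||
                  (abs(err - best$err) <= 1e-15 &&
                   (cand$het < best$het ||
                    (cand$het == best$het && cand$n < best$n)))) {
                best <- cand
              }
            }
          }
        }
      }
    }
  }
  if (is.null(best)) NA_character_ else best$formula
}

# constant-intensity EEM on the generator grid
constant_eem <- function(value = 1, em_step = 1) {
  ex <- seq(240, 450, by = 10)
  em <- seq(300, 560, by = em_step)
  eem(ex, em, matrix(value, length(ex), length(em)))
}

# small deterministic peak list
toy_peaks <- function(masses, intensity = 1, sn = 10) {
  tibble::tibble(neutral_mass = masses,
                 intensity = rep_len(intensity, length(masses)),
                 sn = rep_len(sn, length(masses)))
}

# minimal assigned-spectrum tibble for index computations
toy_spectrum <- function(formulas, rel) {
  counts <- parse_formula(formulas)
  tibble::tibble(
    formula = formulas,
    c = counts$c, h = counts$h, n = counts$n,
    o = counts$o, s = counts$s, p = counts$p,
    exact_mass = formula_mass(counts$c, counts$h, counts$n, counts$o,
                              counts$s, counts$p),
    rel_intensity = rel,
    class = classify_formula(counts$c, counts$h, counts$n, counts$o,
                             counts$s, counts$p),
    cram = is_cram(counts$c, counts$h, n = counts$n, o = counts$o,
                   p = counts$p)
  )
}

# small transect configuration for fast end-to-end tests
fast_config <- function(seed = 1, ...) {
  transect_config(seed = seed, n_optics_only = 15, n_formulas = 1200, ...)
}
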