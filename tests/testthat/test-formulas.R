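# Formula arithmetic, validity, classification and per-sample indices.

test_that("DBE matches the valence formula on worked examples", {
  expect_equal(dbe(1, 4), 0)                    # CH4, saturated limit
  expect_equal(dbe(6, 6), 4)                    # benzene
  expect_equal(dbe(10, 15, n = 1), 4)           # C10H15O5N: 1 + 10 - 7.5 + 0.5
  expect_equal(dbe(10, 15), 3.5)                # odd H without N: half-integer
})

test_that("AImod handles worked examples and degenerate denominators", {
  expect_equal(aimod(1, 4), 0)                  # CH4: numerator 0 (-1 -> 0)
  expect_equal(aimod(6, 6), 4 / 6)
  expect_equal(aimod(16, 10), 0.75)             # pyrene
  # denominator <= 0 or negative numerator clamp to zero
  expect_equal(aimod(2, 4, o = 4), 0)
  expect_equal(aimod(3, 8), 0)
})

test_that("validity rules enforce ratio windows and DBE parity", {
  expect_true(is_valid_formula(6, 10, o = 5))   # C6H10O5
  expect_false(is_valid_formula(1, 10))         # H/C = 10
  expect_false(is_valid_formula(10, 15, o = 2)) # DBE 3.5, parity violation
  expect_false(is_valid_formula(10, 15, o = 20, n = 1)) # O/C = 2
  expect_false(is_valid_formula(6, 8, n = 5, o = 2))    # N bound
})

test_that("CRAM windows require all three DBE ratios simultaneously", {
  expect_true(is_cram(20, 26, o = 10))          # DBE 8: 0.40 / 0.308 / 0.80
  expect_false(is_cram(6, 6))                   # no oxygen
  expect_false(is_cram(30, 60, o = 2))          # DBE 1: DBE/C below window
})

test_that("classification applies rules in order and partitions", {
  expect_equal(classify_formula(6, 12, o = 6), "sugars")        # O/C = 1
  expect_equal(classify_formula(16, 10), "black_carbon")        # AImod 0.75
  expect_equal(classify_formula(16, 26, o = 8), "unsaturated_aliphatic")
  expect_equal(classify_formula(10, 17, n = 1, o = 3), "peptides")
  expect_equal(classify_formula(20, 42, o = 2), "saturated_fatty_acids")
  # every valid composition gets exactly one of the known labels
  set.seed(11)
  cs <- sample(5:40, 300, replace = TRUE)
  hs <- pmax(1, round(cs * runif(300, 0.3, 2.5)))
  os <- pmin(round(cs * runif(300, 0, 1.2)), 40)
  cls <- classify_formula(cs, hs, o = os)
  expect_true(all(cls %in% compound_classes()))
  expect_length(cls, 300)
})

test_that("S/N filtering is strict and assignment thresholds differ", {
  pk <- toy_peaks(c(200, 300, 400), sn = c(3.9, 4.1, 5.1))
  expect_equal(sn_filter(pk, 4)$sn, c(4.1, 5.1))
  expect_equal(nrow(sn_filter(toy_peaks(1:3 * 100, sn = 3), 4)), 0)
  expect_equal(nrow(sn_filter(toy_peaks(1:3 * 100, sn = 10), 5)), 3)
  # detection keeps sn > 4 but normalisation only covers sn > 5
  a <- assign_formulas(toy_peaks(c(162.052824, 180.063388),
                                 sn = c(4.5, 10)))
  expect_true(all(a$assigned))
  expect_true(is.na(a$rel_intensity[1]))
  expect_equal(a$rel_intensity[2], 1)
})

test_that("assignment finds exact-mass candidates and flags the rest", {
  a <- assign_formulas(toy_peaks(162.052824))
  expect_equal(a$formula, "C6H10O5")
  expect_lt(abs(a$mass_error_ppm), 0.1)
  # outside the configured mass window: retained but unassigned
  rules <- formula_rules(mass_range = c(154, 817))
  b <- assign_formulas(toy_peaks(c(162.052824, 1000)), rules = rules)
  expect_equal(b$assigned, c(TRUE, FALSE))
  expect_true(is.na(b$formula[2]))
  expect_warning(assign_formulas(toy_peaks(numeric(0))), "no peaks")
})

test_that("assignment is invariant to intensity scaling", {
  set.seed(5)
  lib <- build_formula_library(300)
  sp <- generate_spectrum(lib, library_dbe(lib, 0.4), noise_cv = 0)
  a1 <- assign_formulas(sp)
  sp2 <- dplyr::mutate(sp, intensity = intensity * 37.5)
  a2 <- assign_formulas(sp2)
  expect_equal(a1$rel_intensity, a2$rel_intensity, tolerance = 1e-12)
  expect_identical(a1$formula, a2$formula)
})

test_that("[M-H]- m/z input is converted back to neutral mass", {
  mz <- 162.052824 - 1.00727646
  a <- assign_formulas(toy_peaks(mz), adduct = "mh")
  expect_equal(a$formula, "C6H10O5")
})

test_that("degradation index follows the marker intensity ratio", {
  mk <- ideg_markers()
  neg <- mk$formula[mk$role == "neg"]
  pos <- mk$formula[mk$role == "pos"]
  # all pos zero, some neg positive -> 1
  sp <- toy_spectrum(c(neg, pos), c(rep(0.1, 5), rep(0, 5)))
  expect_equal(ideg(sp), 1)
  # equal sums -> 0.5
  sp <- toy_spectrum(c(neg, pos), rep(0.1, 10))
  expect_equal(ideg(sp), 0.5)
  # neg (1,1,1,1,1), pos (3,0,0,0,0) -> 5/8
  sp <- toy_spectrum(c(neg, pos), c(rep(1, 5), 3, 0, 0, 0, 0) / 8)
  expect_equal(ideg(sp), 5 / 8)
  # no marker present -> NA with warning
  sp <- toy_spectrum("C6H10O5", 1)
  expect_warning(v <- ideg(sp), "undefined")
  expect_true(is.na(v))
})

test_that("intensity-weighted indices average correctly", {
  sp <- toy_spectrum(c("C10H12O5", "C20H24O10"), c(0.5, 0.5))
  expect_equal(weighted_index(sp, "dbe"), mean(dbe(c(10, 20), c(12, 24))))
  sp <- toy_spectrum(c("C6H10O5", "C6H10O5"), c(1, 0))[1, ]
  expect_equal(weighted_index(sp, "exact_mass"), formula_mass(6, 10, o = 5))
  # weights (0.25, 0.75) on masses about (200, 400) scale linearly
  sp <- toy_spectrum(c("C10H12O5", "C20H24O10"), c(0.25, 0.75))
  m1 <- formula_mass(10, 12, o = 5); m2 <- formula_mass(20, 24, o = 10)
  expect_equal(weighted_index(sp, "exact_mass"), 0.25 * m1 + 0.75 * m2)
  expect_warning(weighted_index(toy_spectrum("C6H10O5", NA_real_)),
                 "empty")
})

test_that("molecular index set partitions class percentages", {
  sp <- toy_spectrum("C16H18O8", 1)          # single highly unsaturated
  m <- molecular_index_set(sp)
  expect_equal(m$pct_highly_unsaturated, 100)
  expect_equal(m$pct_sugars + m$pct_black_carbon + m$pct_polyphenols +
                 m$pct_peptides + m$pct_unsaturated_aliphatic +
                 m$pct_saturated_fatty_acids + m$pct_other, 0)
  set.seed(7)
  lib <- build_formula_library(400)
  sp <- assign_formulas(generate_spectrum(lib, library_dbe(lib, 0.5),
                                          noise_cv = 0.13))
  m <- molecular_index_set(sp)
  total <- sum(unlist(m[grep("^pct_", names(m))])) - m$pct_cram
  expect_equal(total, 100, tolerance = 1e-9)
})

test_that("fresh end-member carries more unsaturated aliphatics", {
  set.seed(3)
  lib <- build_formula_library(800)
  fresh <- assign_formulas(generate_spectrum(lib, library_dbe(lib, 0),
                                             noise_cv = 0))
  degr <- assign_formulas(generate_spectrum(lib, library_dbe(lib, 1),
                                            noise_cv = 0))
  expect_gt(molecular_index_set(fresh)$pct_unsaturated_aliphatic,
            molecular_index_set(degr)$pct_unsaturated_aliphatic)
  # CRAM overlap with highly unsaturated is reported, not assumed
  overlap <- mean(degr$class[degr$cram] == "highly_unsaturated")
  expect_true(overlap >= 0 && overlap <= 1)
})
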