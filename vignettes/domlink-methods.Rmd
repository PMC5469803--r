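---
title: "Linking optical and molecular signatures of marine DOM: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking optical and molecular signatures of marine DOM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`domlink` estimates molecular-level properties of marine dissolved organic
matter (DOM) from optical measurements. This vignette documents the models,
the tunable parameters, the synthetic-data generator that makes the chain
testable offline, and the design decisions taken where the underlying
methodology left genuine freedom.

## The analysis chain

1. **Optical parameters.** EEMs (excitation 240–450 nm in 10 nm steps, 22
   emission scans over 300–560 nm) are blank-corrected and expressed in
   normalized fluorescence intensity units (NFIU). Rayleigh (first and
   second order) and water-Raman scatter ridges are masked and bridged by
   linear interpolation along each emission scan. The classical peaks are
   read at fixed excitation/emission pairs — A (250/435), C (340/440),
   M (320/410), T (280/350), B (270/304 nm) — as the nearest grid node;
   carbon-specific ("starred") intensities divide by DOC in mg C L⁻¹
   (1 µmol C = 12.011 × 10⁻³ mg C). Decadal absorbance converts to the
   Napierian absorption coefficient a(λ) = ln(10)·A(λ)/ℓ. The indices are
   FI = I(370, 470)/I(370, 520); FrI = I(310, 380)/max I(310, 420–435);
   BIX = I(310, 380)/I(310, 430); HIX = ∫₄₃₅⁴⁸⁰ I(260, em) d em /
   ∫₃₀₀³⁴⁵ I(260, em) d em, both integrals by the trapezoid rule on the
   native emission grid so the value is invariant to the grid step.

2. **Molecular formulae.** Neutral monoisotopic masses with S/N > 4 are
   matched against all CHNOSP compositions satisfying H/C ∈ [0.3, 2.5],
   O/C ∈ [0, 1.2], N ≤ 4, S ≤ 2, P ≤ 1 and an integer non-negative DBE
   (DBE = 1 + C − H/2 + N/2 + P/2), within a relative tolerance of
   0.5 ppm; the candidate with the smallest |ppm error| wins, ties broken
   by fewer heteroatoms (N+S+P), then fewer N. Intensities of assigned
   peaks with S/N > 5 are normalised to sum to one per sample; the two
   thresholds are separate configuration knobs because detection and
   semi-quantitative normalisation are distinct steps. Compound classes
   are assigned by the first matching rule in a fixed order (sugars by
   O/C > 0.9 first, so high-O/C aromatics cannot shadow them; then black
   carbon, polyphenols and highly unsaturated via AImod; then peptides /
   unsaturated aliphatics / saturated fatty acids via H/C and N). CRAM is
   an overlay flag (DBE/C ∈ [0.30, 0.68], DBE/H ∈ [0.20, 0.95],
   DBE/O ∈ [0.77, 1.75]), not a class.

3. **Screening.** Every formula's relative intensity across samples is
   rank-correlated (mid-ranks on ties) with every optical parameter.
   The critical coefficient comes from inverting the Student-t
   approximation, r_crit = t_q/√(t_q² + n − 2); at n = 29 and 99 %
   one-sided confidence this gives 0.43 (two decimals). Formulae absent
   from a sample are zero-filled — absence is informative for ranks — and
   a minimum-presence filter (≥ 3 samples by default) removes all-zero
   rows. No multiple-testing correction is applied by default, matching
   the per-pair confidence convention of this literature; a threshold
   override is exposed.

4. **Proxy regressions.** Each intensity-weighted molecular index is
   regressed on (peak C*, peak T*, θ) by OLS. Reported per model:
   coefficients, standardised betas b·sd(x)/sd(y), SEE% = 100·RMSE/mean(y),
   R² and the overall F-test p. The cross-validation ensemble redraws
   floor(0.8·n) training rows (23 of 29) 1000 times, refits, predicts the
   held-out remainder and reports per-coefficient means (SDs) and the mean
   absolute percentage error. Predictions for optics-only samples use the
   ensemble mean coefficients, after mapping the second fluorometer onto
   the reference scale by OLS over the dual-measured samples.

## The synthetic transect

The generator emulates a trans-basin cruise: 7 stations spanning
longitudes −5° to 32°E, casts at 75, 500, 1000 and 2500 m (plus extra
shallow casts to reach 29 fully characterised samples), and 400
optics-only casts measured on a second fluorometer. Its backbone is a
single degradation latent d(z) = 1 − exp(−z/500 m): DOC decays as
42 + 18·exp(−z/300 m) µmol C L⁻¹, θ falls affinely from 14.5 °C near the
deep chlorophyll maximum to 13.0 °C at depth with a west-to-east basin
warming offset drawn once per station from U(0, 9) °C, humic-like
fluorescence (peak C*) rises with d, protein-like (peak T*) falls, and
HIX rises while FI, FrI, BIX and a254* fall, all with mean-preserving
lognormal variability.

Molecular composition comes from two end-member intensity distributions
over a library of ~2500 valid formulae sampled to match open-ocean class
abundances (highly unsaturated 70 %, unsaturated aliphatics 14 %,
polyphenols 12 %, peptides 2.5 %, saturated fatty acids 0.8 %, sugars
0.6 % by number). The "fresh" member tilts towards low DBE and aliphatic
classes, the "degraded" member towards high-DBE highly-unsaturated and
CRAM formulae; a common exp(−mass/100 Da) decay keeps the
intensity-weighted MW near open-ocean values (~375 Da at mid-mix). Each
sample's DBE target — generated from the proxy-model equations evaluated
on the sample's *observed* optics plus Gaussian residuals — anchors the
mixing fraction f by bisection to 10⁻⁶; Ideg, class percentages and CRAM%
then *emerge* from the library rather than being forced, so their
regressions on optics are only approximately the generative coefficients.
Per-peak lognormal noise with CV 13 % reproduces replicate-spectrum
reproducibility of FT-ICR-MS measurements.

EEMs are sums of five 2-D Gaussian fluorophores (σ_ex = 25, σ_em = 30 nm)
centred at the classical peak coordinates; the five amplitudes are solved
from a 5 × 5 linear system so the noiseless, scatter-free surface
evaluates *exactly* to the requested peak intensities at the peak nodes.
First/second-order Rayleigh and Raman ridges are superimposed and must be
removed by the optics stage; ridge positions were chosen to avoid every
queried node (peaks and index coordinates), so noiseless recovery is
limited only by ridge tails (< 1 %).

### Calibrated variability

Three generator choices were derived, once, from explicit variance
budgets rather than picked ad hoc:

- **Residual SDs** of the index targets equal the documented percent
  standard errors of estimate times a typical index mean: 0.08 (DBE),
  0.035 (Ideg), 0.65 (UA %), 0.57 (CRAM %).
- **Predictor variability.** With all three predictors driven by the
  single depth latent the design matrix is near-singular and no estimator
  could recover coefficients at n = 29. Real basins decouple these
  quantities (protein-like fluorescence is the patchiest FDOM component;
  θ varies west–east independently of depth), so peak C* carries sdlog
  0.30, peak T* sdlog 0.60 and θ the U(0, 9) °C station offset. These
  values follow from requiring the OLS standard error of each coefficient
  to sit at or below its documented ensemble SD
  (SE(b_j) = σ_y/(√(n−1)·unique-sd(x_j))).
- **Emergent-index contrast.** The ten degradation-index markers are
  given strong end-member contrast (numerator set 20× heavier in the
  degraded member and vice versa), and the end-member DBE gap is kept
  moderate (≈ 5.6 → 9.0), so that the emergent Ideg/UA/CRAM signals
  across the realised mixing range exceed their measurement noise by the
  documented margin (measured-vs-modeled R² > 0.65). Total covariance
  factorises approximately as R²(index, optics) ≈ R²(DBE target | optics)
  × R²(index | f); both factors were sized from this identity.

### What the generator does not emulate

Hydrographic structure (water-mass mixing, salinity maxima), chlorophyll,
photochemistry, inner-filter effects, instrument drift, ¹³C
isotopologues, and electrospray ionisation selectivity. Passing tests on
synthetic transects therefore demonstrate that the *pipeline* is correct
and well-calibrated under a plausible covariance structure — not that any
particular ocean obeys the generative model.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| assignment tolerance | 0.5 | ppm | FT-ICR-MS mass accuracy at 15 T |
| S/N detection / normalisation | 4 / 5 | — | detection limit vs semi-quantitative set |
| element bounds | C≤60, H≤122, N≤4, O≤40, S≤2, P≤1 | — | covers the 154–817 Da marine DOM window |
| screen confidence / tails | 0.99 / one-sided | — | one-sided reproduces r_crit = 0.43 at n = 29; two-sided gives 0.47 |
| minimum presence | 3 | samples | rank correlation undefined on all-zero rows |
| train fraction / reps | 0.8 / 1000 | — | floor(0.8·29) = 23 train, 6 test |
| scatter half-widths | 15 / 20 / 5 | nm | first- and second-order Rayleigh; Raman at the 3400 cm⁻¹ shift |
| emission step | 1 | nm | finest common instrument step; configurable |
| peak noise CV | 0.13 | — | replicate-spectrum reproducibility |

## Resolved ambiguities

Where the methodology as usually reported is ambiguous, the package picks
one behaviour and exposes the alternative:

- **HIX** uses the non-normalised ratio Σ₄₃₅₋₄₈₀/Σ₃₀₀₋₃₄₅ (not the
  normalised variant with the numerator band added to the denominator).
- **FrI** is evaluated at *excitation* 310 nm; descriptions reading
  "310 emission" are treated as shorthand for the excitation wavelength,
  consistent with BIX.
- **Peak picking** reads the single nearest node; a ±window emission
  average is available (`em_window`) but off by default.
- **Intensity share** of a flagged set is the mean across samples of its
  summed relative intensity (option: pooled).
- **θ** enters the regressions raw, not standardised — the intercepts
  only make sense on raw scales.
- **Ideg markers**: the published ten-formula marker set belongs to the
  original degradation-index reference; `ideg_markers()` ships a clearly
  documented synthetic stand-in (numerator set CRAM-leaning, denominator
  aliphatic-leaning in the 280–440 Da region) and real-data users should
  supply the published set.
- **Input masses** are neutral monoisotopic; `adduct = "mh"` converts
  [M−H]⁻ m/z by adding one proton mass.
- **No outlier removal** anywhere: divergent points in the
  measured-vs-modeled comparison are flagged (> 3 residual SDs), never
  dropped.

## Numerical choices

Scatter interpolation preserves constants exactly and is idempotent
(cells outside ridges are untouched). Peak-node ties break towards the
lower wavelength. The mixing fraction is solved by bisection to 10⁻⁶ even
though the weighted DBE is affine in f for normalised end-members — the
solver stays correct if a user supplies unnormalised weights. Candidate
enumeration for assignment precomputes the full valid-composition library
(~6 × 10⁵ entries at default bounds) once per rule set and binary-searches
it per peak; an exhaustive per-peak loop serves as the test oracle.
Rank-deficient regression designs fail loudly, naming the collinear
columns; cross-validation redraws rank-deficient training subsets and
counts the redraws.

## Problem sizes

The shipped tests and the acceptance script run the study-scale
configuration: 29 fully characterised samples, 400 optics-only casts,
~2500-formula library, 10⁴ null formulae for the type-I check, 1000
cross-validation repetitions. A full pipeline run takes well under a
minute on one CPU.

## Known limitations

- Formula assignment considers CHNOSP only (no halogens, no isotopologue
  verification) and picks a single best candidate; it does not implement
  homologous-series (Kendrick) network assignment.
- The screen reports per-pair flags at a fixed confidence; with thousands
  of formulae the family-wise error is large by construction, as is
  conventional for this exploratory use.
- The default Ideg marker set is a synthetic stand-in (above).
- PARAFAC decomposition, inner-filter correction and Raman-unit
  normalisation are out of scope; the optics stage assumes NFIU-scaled,
  blank-corrected EEMs.
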