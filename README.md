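# domlink

Optical spectroscopy of marine dissolved organic matter (DOM) — fluorescence
excitation–emission matrices (EEMs) and UV absorption — is fast and cheap;
ultrahigh-resolution mass spectrometry (FT-ICR-MS) is neither, but it resolves
thousands of molecular formulae. When the two covary, optical measurements can
serve as proxies for molecular composition over whole ocean basins. `domlink`
implements that proxy chain end to end for R users working on open-ocean DOM:

- **optics**: classical fluorescence peaks A, C, M, T, B picked from EEMs at
  their canonical excitation/emission pairs, carbon-specific (DOC-normalised)
  intensities, the Napierian absorption coefficient *a*₂₅₄, peak ratios, and
  the FI, FrI, BIX and HIX fluorescence indices; mathematical removal of
  Rayleigh and Raman scatter ridges.
- **formulas**: CHNOSP molecular-formula assignment to neutral masses at
  sub-ppm tolerance with standard marine-DOM validity rules, compound-class
  labels from O/C, H/C and the modified aromaticity index AImod,
  carboxyl-rich alicyclic molecule (CRAM) flags, the degradation index Ideg,
  and intensity-weighted per-sample indices (MW, DBE, H/C, O/C, class
  percentages).
- **linkage**: Spearman rank screening of every formula's relative intensity
  against every optical parameter at a t-derived critical coefficient
  (r > 0.43 for n = 29 at the 99 % one-sided confidence level), with
  per-parameter counts, signal-intensity shares and van Krevelen tables.
- **proxy models**: cross-validated multiple linear regressions
  `index ~ peak C* + peak T* + θ` (1000 random 80/20 splits), standardised
  coefficients, percent standard error of estimate, held-out error,
  instrument intercalibration, and prediction of molecular indices for
  optics-only samples.
- **synthetic transect**: a generator that emulates a trans-basin cruise —
  29 fully characterised samples plus 400 optics-only casts over a
  depth-driven degradation gradient — with known ground truth, so the whole
  chain is testable offline.

The core statistical object is the proxy regression

    y = b0 + bC · peakC* + bT · peakT* + bθ · θ + ε,

where `y` is an intensity-weighted molecular index (DBE, Ideg, unsaturated
aliphatics %, CRAM %), `peakC*`/`peakT*` are carbon-specific humic-like and
protein-like fluorescence intensities (NFIU L mg⁻¹ C) and `θ` is potential
temperature (°C). Coefficients are reported as the mean (SD) over the
cross-validation ensemble.

## Worked example

```r
library(domlink)
library(dplyr)

pl <- run_transect_pipeline(transect_config(seed = 1), reps = 1000)

tidy(pl$ensembles$dbe)
#> # A tibble: 4 × 3
#>   term        estimate std.error
#> 1 (Intercept)   7.83    0.0617
#> 2 peak_c_star   0.337   0.0165
#> 3 peak_t_star  -0.0201  0.000914
#> 4 theta_c      -0.0181  0.00230

glance(pl$ensembles$dbe)$mean.error.pct
#> [1] 0.710

pl$comparison$summary
#> # A tibble: 4 × 7
#>   index                     slope intercept r_squared  p_value     n n_divergent
#> 1 dbe_w                     0.931     0.535     0.931 3.19e-17    29           0
#> 2 ideg                      0.807     0.127     0.808 3.63e-11    29           0
#> 3 pct_unsaturated_aliphatic 0.929     1.58      0.928 5.95e-17    29           0
#> 4 pct_cram                  0.816     5.37      0.818 1.68e-11    29           0

pl$intercalibration$peak_c
#> <intercalibration> peak_c = -0.0272 + 0.7637 x peak_c_b (R2 = 0.955, ...)
```

Reading the output: the DBE ensemble mean coefficients (0.34 on peak C*,
−0.020 on peak T*, −0.018 on θ, intercept 7.8) recover the generative model
within the ensemble spread, with a 0.7 % mean held-out error; regressing
modeled on measured indices gives R² of 0.81–0.93 for the four indices; and
the second fluorometer's peak C readings map onto the reference scale with
R² = 0.955 over the 29 dual-measured samples. Predicted indices for the 400
optics-only casts are in `pl$predicted` (`pred_dbe_w`, `pred_ideg`, ...).

Individual stages compose with the pipe for real data:

```r
eem <- read_eem_csv("eem_S01_0075m.csv") |> remove_scatter()
opt <- optical_index_set(eem, read_absorbance_csv("abs_S01_0075m.csv"),
                         doc_umol = 57)
assigned <- read_peaks_tsv("peaks_S01_0075m.tsv") |> assign_formulas()
molecular_index_set(assigned)
```

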