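Package: domlink
Title: Linking Optical and Molecular Signatures of Marine Dissolved Organic Matter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to relate optical measurements of marine dissolved organic
    matter (excitation-emission fluorescence peaks and indices, UV absorption)
    to ultrahigh-resolution mass-spectrometric molecular signatures. Provides
    molecular formula assignment with validity rules and compound-class
    labelling (including CRAM and the degradation index), extraction of
    classical fluorescence peaks and indices (FI, FrI, BIX, HIX) from EEMs,
    per-formula Spearman rank screening against optical parameters, and
    cross-validated multiple linear regression proxy models that estimate
    intensity-weighted molecular indices (DBE, Ideg, unsaturated aliphatics,
    CRAM) from carbon-specific fluorescence and temperature. A synthetic
    transect generator produces ground-truth datasets with controlled
    optical-molecular covariance for testing every stage offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    ggplot2,
    jsonlite,
    readr,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
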