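Package: atrigg
Title: Bovine Serum IgG Quantification from ATR Mid-Infrared Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A chemometric pipeline for quantifying immunoglobulin G (IgG) in
    bovine serum from attenuated total reflectance (ATR) mid-infrared spectra
    of dried serum films. Provides a synthetic-data generator for replicate
    dried-film spectra with known IgG truth, plain-text (PRN + CSV manifest)
    spectrum input/output, Savitzky-Golay smoothing and derivative filters,
    SNV and vector normalization, per-wavenumber Dixon Q-test replicate
    outlier screening, PLS1 regression (NIPALS) with Monte Carlo
    cross-validation selection of the number of latent factors, and a full
    method-agreement and diagnostic evaluation (Pearson and Lin concordance
    correlation, Bland-Altman limits of agreement, RPD/RER, modified CV*, and
    2x2 diagnostic characteristics for failure of transfer of passive
    immunity at the 1000 mg/dL cut-off).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
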