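Package: fiefin
Title: Flow Infusion Electrospray Mass Spectrometry Metabolite Fingerprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for nominal-mass metabolite fingerprinting by flow infusion
    electrospray-ionization mass spectrometry (FIE-MS). Builds fingerprint
    matrices from centroided peak lists (integer m/z binning, baseline
    subtraction, log10 transform, total-ion-current normalization), fits
    principal-component linear discriminant analysis (PC-LDA) models with
    eigenvalue (Tw) adequacy calls, assesses class separation by bootstrapped
    random-forest margin, AUC and accuracy, ranks explanatory signals by an
    ensemble of random-forest importance, per-feature AUC and Student's t-test,
    groups selected signals into Pearson-correlation clusters, screens
    categorical metadata for pairwise chi-squared associations with Bonferroni
    control, and annotates accurate masses with cation adducts and 13C
    isotopologues by ppm matching. Includes a synthetic-data generator that
    emulates the statistical structure of multi-class fingerprint experiments
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
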