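Package: etdprep
Title: Pre-Processing and Precursor Charge Determination for ETD Tandem Mass
    Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for pre-processing electron transfer dissociation (ETD)
    MS/MS peak lists before sequence-library searching, and for determining
    unknown precursor charge states from the spectra themselves. Implements
    removal of charge-reduced precursor peaks and their neutral-loss regions
    using mass-proportional windows, a two-stage noise filter (deisotoping
    plus top-h retention in a sliding m/z window), extraction of
    charge-reduced precursor and neutral-loss intensity features, a linear
    discriminant classifier over candidate charge states with
    posterior-probability-driven assignment strategies (Top 1, Top 1/Top 2,
    1/2/All), a seedable synthetic ETD spectrum generator with ground-truth
    annotations, and MGF input/output with an end-to-end pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
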