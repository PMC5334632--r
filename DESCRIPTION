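Package: apascreen
Title: Screening of 3-Alkyl Pyridine Alkaloids in Sponge LC-MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dereplication and prioritization of 3-alkyl pyridine alkaloids
    (3-APAs) from untargeted LC-MS metabolomics of marine sponge extracts.
    Provides an exact monoisotopic mass engine for CHNO formulas, a curated
    and combinatorially expanded 3-APA mass library (cyclostellettamines,
    haliclamines, viscosamines, viscosalines), diagnostic-fragment screening
    of two-function data-independent (MSE) acquisitions, pseudo-MS3 isobar
    resolution by ion-mobility drift time, PCA-based prioritization of
    specimens against cell-viability data, and a synthetic-data generator
    emulating a 28-specimen sponge cohort for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
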