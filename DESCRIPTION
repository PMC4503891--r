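Package: myofilquant
Title: Myofilament Phosphorylation Stoichiometry and In Vitro Motility
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free mass-balance quantification of site-specific
    troponin I and alpha-tropomyosin phosphorylation and troponin I
    C-terminal truncation from extracted-ion-chromatogram peak areas,
    together with in vitro motility analysis of actin filament sliding
    (per-filament velocities, percent moving, motility index) and Hill
    fitting of velocity-pCa curves. Includes synthetic-data generators
    that emulate paired untreated/phosphatase-treated tryptic-digest
    LC-MS runs and filament-tracking videos with known ground truth, so
    every stage of the pipeline is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
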