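Package: neosurv
Title: Neoantigen Cataloging and Survival Stratification for Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native pipeline for per-patient neoantigen
    cataloging from somatic missense variants and for relating neoantigen
    load and quality to patient survival and tumor-microenvironment state.
    Enumerates mutant/wild-type 9-mer peptide pairs, applies an MHC class I
    binding filter cascade (percent rank, IC50), computes the differential
    agretopicity index (DAI) and quality tiers, attributes candidates to HLA
    loci, screens neoepitopes against a local epitope catalog with emphasis
    on TCR-contact positions, and stratifies cohorts for Kaplan-Meier /
    log-rank analysis (quartile and mean splits) including bootstrap-stable
    immune gene-set clustering.  Ships a fully configurable synthetic-cohort
    generator and a deterministic position-weight toy binding predictor so
    the whole pipeline runs and is testable without external services.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    survival,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
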