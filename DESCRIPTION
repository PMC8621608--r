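Package: cnvtrio
Title: Trio-Based De Novo Copy Number Variant Screening from Dye-Swap Array CGH
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a two-stage array-CGH
    screening and trio-based de novo copy number variant (CNV) calling
    pipeline for mouse germline mutagenesis cohorts. Provides a synthetic
    cohort simulator (dye-swap log2-ratio signals on a two-tier probe map,
    planted inherited and de novo deletions/duplications, qPCR dilution
    plates, Weibull lifespans with multiplicative hazards), the two-screen
    probe positivity and confirmation rules, family analysis to isolate de
    novo events, candidate aggregation with Type S/L classification and
    interval estimation, relative-standard-curve qPCR confirmation, and the
    cohort statistics layer (Fisher's exact contingency tests on
    mice-with-CNV tallies, geometric size statistics with F/t tests on
    logs, Grubbs-based short-lifespan exclusion, and Cox proportional
    hazards regression on lifespan). All user-facing functions take and
    return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
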