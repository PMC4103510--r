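Package: polymirts
Title: Polymorphisms in MicroRNA Target Sites of 3'UTRs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts microRNA target sites on 3' untranslated regions
    (canonical seed matches and non-canonical sites containing a single
    G:U wobble or seed mismatch), intersects them with 3'UTR polymorphisms,
    classifies seed versus compensatory-region hits, re-evaluates sites on
    the alternate allele to call site loss, gain or type change, and
    prioritizes candidate microRNAs by brain expression. Also provides
    scrambled-control normalization and classical statistics (one-way and
    two-way ANOVA with Bonferroni post-hoc tests, paired t-tests) for
    dual-luciferase, densitometry and ELISA reporter assays, exact carrier
    counting and Fisher tests for case/control genotype screens, and seeded
    generators of synthetic inputs with ground-truth labels for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
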