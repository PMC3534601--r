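Package: xsexbias
Title: Sex-Biased Gene Expression Analysis for the Mouse X Chromosome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for screening sex-biased gene
    expression on the mammalian X chromosome from multi-tissue log2
    expression matrices. Provides per-probe Wilcoxon rank-sum and Welch t
    screening between sexes, chromosome-class tabulation with Fisher exact
    enrichment/depletion contrasts (including exclusion of known
    X-inactivation escapees), cross-tissue consistency classification with
    detection of small (<50 kb) female-biased gene clusters, and
    phylostratigraphic gene-age analysis. Includes a seeded synthetic-data
    generator with planted chromosome-aware effects for calibration and
    power testing, and packaged fixtures transcribed from published summary
    tables of sex-biased expression in six somatic mouse tissues.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
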