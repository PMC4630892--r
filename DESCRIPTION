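Package: gencor
Title: Across-Breed Genomic Correlation, SNP Selection and GBLUP Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for harnessing two unrelated populations in genomic
    selection. Builds pedigree numerator relationship matrices and blended
    VanRaden genomic relationship matrices from any SNP subset, estimates
    genomic correlations and the fraction of missing heritability with a
    bi-variate average-information REML engine, runs within-breed mixed-model
    association scans with a polygenic background, constructs sign-consistent
    and sign-discordant SNP lists and their genomic relationship matrices,
    and validates GBLUP predictions (accuracy and dispersion bias) across
    breed-by-sex calibration and validation schemes. Includes a two-breed
    gene-drop simulator with known quantitative-trait architecture for
    parameter-recovery studies.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
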