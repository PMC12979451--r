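Package: richclubr
Title: Rich-Club Organization Analysis of Structural Brain Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing rich-club organization in structural brain
    networks built from tractography streamline counts: edge-existence
    thresholding, binary degree and group-averaged networks, rich-club
    coefficient curves normalized against degree-preserving random networks,
    hub identification with rich/feeder/local edge classification,
    class-wise connectivity strength and density, permutation-based group
    contrasts with false discovery rate control, covariate-adjusted partial
    correlations, reconstruction of ANOVA, t and chi-squared statistics from
    published summary tables, and a synthetic cohort generator that emulates
    a four-group childhood-maltreatment by depression design for end-to-end
    testing without subject data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
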