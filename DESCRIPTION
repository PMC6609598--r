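Package: megaexpr
Title: Mega-Analysis of Case-Control Expression Studies
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pools per-gene log2 fold changes across independently collected
    case-control expression studies ("mega-analysis") under fixed- and
    random-effects inverse-variance models, with DerSimonian-Laird
    between-study variance, Cochran's Q and I-squared heterogeneity
    statistics, heterogeneity-driven model selection and significance
    filtering. Also provides study-covariate regression of effect sizes,
    gene-set overlap testing (right-tail Fisher), hypergeometric
    over-representation analysis with Benjamini-Hochberg correction,
    GEO Series Matrix ingestion, and a synthetic multi-study generator
    with known ground truth for validation.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
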