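Package: ivstruct
Title: Spatially Structured Intraspecific Variability in Tree Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how large observed intraspecific variability (IV)
    in individual attributes such as tree growth can emerge from unobserved,
    spatially structured environmental dimensions. Provides a virtual-landscape
    simulator pairing a deterministic "perfect knowledge" response model with
    an "imperfect knowledge" hierarchical Bayesian model that absorbs
    unobserved environmental variation into individual random effects;
    hierarchical growth models for clonal trials and multi-species forest
    inventories with variance partitioning among random effects; census
    processing (annualized growth, filtering, competition indices); and
    spatial diagnostics (Moran's I screening, intra- versus interspecific
    semivariance comparison, empirical semivariograms). Synthetic clonal-trial
    and forest-inventory generators with known truth make every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
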