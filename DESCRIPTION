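Package: adaptmol
Title: Target-Conditional Molecular Generation with Adapter Fine-Tuning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A target-conditional autoregressive molecular generator over
    SELFIES strings. Implements a SELFIES codec for the neutral organic
    subset, a decoder-only transformer with target-conditioned
    cross-attention and bottleneck adapter modules, pre-training and an
    alternating adapter/main fine-tuning schedule with a twice-repeated
    cosine learning rate, temperature sampling, de-novo design metrics
    (valid, unique@k, novel), 1-Wasserstein property-distribution
    comparison, physicochemical profiling, and gradient-boosted QSAR
    activity scoring. Includes a seeded synthetic-data module that emulates
    a drug-like pre-training corpus and small target-labelled fine-tuning
    sets with pXC50-style activity labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xgboost,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with RDKit, available as `python` on
    the PATH (used as the cheminformatics backend for validity checks,
    canonical SMILES, descriptors and fingerprints).
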