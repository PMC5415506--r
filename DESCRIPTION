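Package: carotrend
Title: Century-Scale Trends in Avian Body Size and Carotenoid Plumage Colour
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating long-term temporal trends in avian body
    size and carotenoid-based plumage coloration from museum-specimen data.
    Converts reflectance spectra into avian-perceptual chromatic coordinates
    (just-noticeable-difference units) with a receptor-noise limited model of
    tetrachromatic colour vision, summarises chromatic variation by principal
    components anchored to carotenoid chroma, fits per-species mixed models
    of temporal change with residual-autocovariate spatial correction and
    penalized-spline nonlinearity screening, and combines the resulting
    effect sizes in a Bayesian phylogenetic random-effects meta-analysis with
    known sampling variances (heterogeneity I2, phylogenetic signal, and
    effect-on-effect meta-regression). Includes a synthetic-study generator
    with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    nlme,
    mgcv,
    MASS
Suggests:
    metafor,
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
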