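Package: pyromes
Title: Fire-Regime Classification, Tropical Projection and Degradation Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Defines landscape fire regimes from gridded monthly burned-area
    records by hierarchical clustering of twelve fire characteristics (monthly
    and yearly means and coefficients of variation of burned area, fire number
    and fire size), projects regimes onto a larger tropical domain with the
    multivariate environmental similarity surface (MESS), quantifies
    environmental overlap between regions with Schoener's D in PCA-reduced
    spaces, estimates regime-wide and rainfall-decoupled burned-area trends,
    classifies vegetation from NDVI statistics, and summarises tree-loss
    anomalies by regime, region and vegetation class. Ships a synthetic-tropics
    generator with planted ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
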