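Package: adipoindex
Title: Adipocyte Morphometry and the Blubber Adipocyte Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies adiposity from stained blubber histology sections.
    Provides intensity-threshold segmentation of adipose tissue images into
    adipocyte and intervacuolar area, per-cell area measurement under a
    circular cell model, computation of the adipocyte index (AI), and the
    cohort-discrimination statistics used with these metrics: two-sample
    t-tests, Pearson correlations, and binary logistic regression with
    backward likelihood-ratio variable selection, Nagelkerke R-squared and
    Hosmer-Lemeshow goodness of fit. A synthetic-histology generator
    produces packed-disc tissue images with exact ground-truth label masks,
    and a cohort-table simulator produces per-sample metric tables with
    controlled means, correlations and missingness, so the whole pipeline
    can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    png,
    jsonlite,
    withr,
    car,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
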