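Package: villimorph
Title: Morphometry of Placental Villi and Capillaries in H&E Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative morphometry of placental villi and their fetal
    capillaries from light-microscopic images of hematoxylin-and-eosin
    stained tissue sections. Provides image preprocessing (grayscale
    conversion, median filtering, histogram equalization), villous
    segmentation by Otsu thresholding with island removal, capillary
    segmentation combining grayscale morphology with stain color
    deconvolution and CIELAB color thresholding, extraction of ten
    per-subject morphometric features (villous and capillary count, area,
    perimeter, equivalent diameter, and two capillarization indices), and a
    statistical battery: two-sample t-tests, Fisher's linear discriminant
    analysis with leave-one-out accuracy ranking of features, hierarchical
    cluster analysis, and principal component analysis. Includes a
    synthetic-data module that renders H&E-like scenes with ground-truth
    masks and draws cohort feature tables with specified group structure,
    so the whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    ape,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
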