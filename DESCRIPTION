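Package: ki67ng
Title: Semi-Automated Scoring of Ki-67 Nuclear Gradient in H-DAB Immunohistochemistry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A pipeline for quantifying Ki-67 immunostaining patterns in
    brightfield H-DAB tissue images. Performs optical-density transformation
    and colour deconvolution of hematoxylin/DAB stains, nucleus segmentation
    with quality control, nuclear morphometry, and rule-based classification
    of the intranuclear Ki-67 staining pattern ("nuclear gradient": granular
    NG1, perinucleolar-node NG2, homogeneous NG3/4, and mitotic figures).
    Aggregates per-nucleus DAB-positive pixel scores and the proliferation
    index to core and case level, and provides the accompanying statistical
    layer (Spearman correlation with categorisation bands, two-way ANOVA with
    Bonferroni correction, chi-squared/Fisher crosstabs, and Cox
    proportional-hazards models of progression-free disease). A synthetic
    tile and cohort generator supplies pixel-exact ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    survival,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
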