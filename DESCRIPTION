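Package: mucquant
Title: Quantifying Mucocyst Docking, Tip Polarity, and Pooled-Segregant
    Mapping in Tetrahymena
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Image- and sequence-based quantification of regulated
    exocytosis phenotypes in Tetrahymena thermophila.  Segments
    two-channel fluorescence micrographs of Grl-labeled mucocysts and
    Mdl puncta by adaptive thresholding with morphological cleanup,
    measures object-based colocalization against a random-translocation
    null, quantifies tip polarity of puncta on elongated organelles via
    angle and normalized centroid-offset statistics with a
    within-organelle randomization null and two-sample
    Kolmogorov-Smirnov testing, and measures mucocyst docking as the
    peripheral fraction of signal in cross-sectional images.  A second
    arm maps a causal mutation from two phenotype-pooled variant tables
    by allele-frequency contrast scoring with coverage and homozygosity
    filters, smoothed linkage tracks, peak detection, and impact-ranked
    candidate prioritization.  Synthetic-data generators for both
    micrographs and F2 whole-genome-homozygote segregant pools provide
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    tiff,
    utils,
    vcfR,
    withr
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
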