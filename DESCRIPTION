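Package: filamix
Title: Two-Cell-Type Mixture Deconvolution of Filament Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for transcriptome experiments that compare two
    cell types within a multicellular filament (vegetative cells and
    heterocysts of heterocyst-forming cyanobacteria) against whole-filament
    samples across growth conditions. Provides quantile normalization and
    replicate quality control, a no-intercept two-component linear mixing
    model F = a*V + b*Ht with grid-search and bootstrap inference, a
    weighted-residual outlier statistic that flags transcripts degraded
    during cell-type isolation, Welch-test differential-expression
    classification with fold-change thresholds, sample-level PCA and
    functional-category transcript-share profiles, RT-qPCR standard-curve
    relative quantification with reference-gene normalization and
    cell-specificity estimation, and a synthetic-data generator with known
    ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
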