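Package: diaquant
Title: Fragment-Filtered Label-Free Quantification for SWATH/DIA Proteomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Label-free protein quantification for data-independent
    acquisition (SWATH) mass spectrometry. Fragment-level extracted-ion
    chromatogram intensities are screened for quantifiable transitions by
    normalized spectral contrast angle clustering, normalized through a
    hierarchical median-scaling cascade over injection, digestion and
    biological replicates, and rolled up to protein abundances as the median
    of the top three most intense peptides on a configurable logarithm base.
    Companion branches implement the exponentially modified protein abundance
    index (emPAI) from in-silico tryptic digestion, targeted MRM peak-area
    quantification with Benjamini-Hochberg controlled testing, and
    proteome-transcriptome concordance classification. A synthetic-data
    generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
biocViews: Proteomics, MassSpectrometry, Normalization, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
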