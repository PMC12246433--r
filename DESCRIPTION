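Package: secmiR
Title: Endothelial Secretome miRNA Microarray Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for attributing blood-circulating miRNA
    signatures to the endothelial secretome from probe-level miRNA microarray
    data. Implements serial-dilution probe quality control and detection
    thresholding, blank-medium background subtraction, fraction-of-total
    intensity normalisation, intracellular/secretory signature partitioning,
    endothelial-origin classification of serum and plasma miRNAs,
    correlation-matrix block summaries with group tests and PCA, and
    time-course trend classification. Ships a synthetic microarray generator
    emulating the HUVEC culture-grid, dilution-series, time-course and
    blood-panel study designs with serialised ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
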