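Package: dpes
Title: Differential Pathway Expression Scoring for Paired Tumor/Normal RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links the number of de-regulated pathway genes in colon tumors to
    patient survival. Implements a paired tumor/normal nonparametric
    differential-expression test (depth-equalizing binomial thinning, averaged
    standardized Wilcoxon signed-rank statistics, within-pair label-flip
    permutation nulls), gene-set overrepresentation with Benjamini-Hochberg
    control, per-subject quartile-based differential gene expression scores
    (DGES) summed into differential pathway expression scores (DPES), and
    cause-specific Cox proportional-hazards models of DPES tertiles on
    cancer mortality with Kaplan-Meier curves and stage comparisons. Includes
    a negative-binomial paired-cohort simulator with known ground truth and a
    reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    DESeq2,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
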