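Package: epiance
Title: Ancestry Principal Components from SNP-Overlapping Probes on DNA
    Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes genetic-ancestry principal components from Illumina
    DNA methylation array data (450K, EPICv1, EPICv2) when genotyping data
    is unavailable. Beta values at CpG probes that directly overlap common
    SNPs are residualized for technical and biological covariates (control
    probe PCs, cell-type proportion PCs, sex, age) and combined with
    genotype calls from the dedicated rs probes before PCA, yielding
    ancestry PCs whose leading component tracks genetic background rather
    than batch or cell composition. Includes the full preprocessing chain
    (background correction, detection p-values, bead-count and call-rate
    filters, quantile normalization, k-nearest-neighbour imputation), a
    clustering and association evaluation battery (silhouette scores, 3D
    centroid distances, assumption-gated group tests, mixed-model
    likelihood-ratio tests), and a synthetic cohort simulator with known
    ancestry structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    car,
    jsonlite,
    limma,
    lme4,
    stats,
    utils
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
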