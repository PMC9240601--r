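Package: heteroGWAS
Title: Geometric Morphometrics and Single- and Multi-Leaf GWAS for Heterophylly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies heterophylly (multiple leaf morphologies on a single
    plant) from leaf images or outlines via radial semi-landmarks, generalized
    Procrustes alignment, elliptic Fourier descriptors and shape principal
    components, and maps its genetic architecture with two complementary
    genome-wide association scans: per-leaf-type single-leaf scans under LM, Q
    and Q+K (kinship mixed) models, and a multi-leaf scan that models the four
    canopy leaf positions jointly as a multivariate normal with genotype-group
    mean vectors and a shared first-order structured antedependence (SAD(1))
    covariance, tested by likelihood ratio with permutation-derived
    genome-wide thresholds. Includes SNP filtering (mapping quality, missing
    rate, minor allele frequency, depth, exact Hardy-Weinberg test), kinship
    (GRM and KING-robust), linkage-disequilibrium decay fitting, genotype PCA
    for structure covariates, candidate-region assignment from gene models,
    and a fully parameterized synthetic-data generator with known ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    MASS,
    e1071,
    minpack.lm,
    EBImage,
    png,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
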