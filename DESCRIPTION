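Package: snpblup
Title: Joint SNP Effect Estimation, Polygenic Scoring and
    Prediction-Accuracy Extrapolation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for genomic prediction of complex
    traits from genotype arrays. Estimates all SNP effects jointly as
    random effects in mixed linear models (single, effect-size-grouped,
    MAF-stratified and multivariate variance components) by restricted
    maximum likelihood, back-solves SNP-BLUP effects for polygenic
    scoring, evaluates prediction accuracy within and across populations,
    benchmarks against clump-and-threshold GWAS predictors, and
    extrapolates accuracy to larger training sample sizes via the linear
    relationship between inverse squared accuracy and inverse sample
    size. Includes a synthetic cohort generator (Balding-Nichols
    population structure, Gaussian-copula LD blocks, sib pairs, platform
    missingness, configurable trait architectures), PLINK bed/bim/fam
    readers and writers, and the standard genotype, sample, phenotype,
    ancestry and relatedness quality-control filters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
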