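Package: tprspls
Title: Transcriptome-Imputed Polygenic Scores and Behavioral PLS for
    Brain and Symptom Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline linking genotypes to depressive
    symptoms through the brain: transcriptome-based polygenic risk
    scoring (T-PRS) from SNP-imputed cortical gene expression,
    conventional clumping-and-thresholding polygenic scores from GWAS
    summary statistics, genotype quality control with relatedness
    (PIHAT) filtering and identity-by-state multidimensional scaling,
    behavioral partial least squares (PLS) relating scores to
    condition-wise voxel activation with permutation and bootstrap-ratio
    inference and cluster reporting, and sex-stratified bootstrap
    mediation of score-brain-symptom paths. A synthetic-data module
    generates every input with planted structure so the whole chain is
    testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
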