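Package: impanel
Title: Reference Panel Design and Evaluation of Genotype Imputation in
    Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate genotype imputation from SNP-array to
    whole-genome sequence level in multi-breed livestock cohorts.
    Simulates structured, phased sequence panels under a
    Balding-Nichols model with mosaic haplotypes, derives nested
    reference panels from identity-by-state relationships and
    multidimensional scaling, imputes masked array genotypes with a
    diploid Li-Stephens haplotype-copying hidden Markov model, scores
    per-variant imputation accuracy under cross-validation with
    standard exclusion rules, quantifies the information content shared
    between marker panels by Monte Carlo analysis of variance, and
    screens high-impact variants for missing homozygosity with a
    binomial Hardy-Weinberg test, including the analytic sample-size
    and allele-frequency calculators for that test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
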