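Package: stratlink
Title: Stratified Whole-Genome Pedigree Linkage Analysis
Version: 0.1.0
Authors@R: person("Pedigree", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for family-based linkage screens on SNP pedigree data:
    PED/MAP input with validation and pedigree trimming, a marker and sample
    quality-control cascade (call rate, cross-batch presence, Mendelian
    errors, MAF, Hardy-Weinberg exact test, map-position filters, inbreeding
    F), exact parametric two-point LOD and heterogeneity LOD (HLOD) via
    Elston-Stewart peeling, Lander-Green multipoint inheritance-vector HMM
    with nonparametric S_all scoring and Kong-Cox linear and exponential
    allele-sharing LOD, inter-marker LD clustering, genotyping-error
    detection, clinical stratification with a conditional permutation test
    for chromosome-wide and genome-wide empirical significance, Monte-Carlo
    power estimation conditional on observed phenotypes, candidate-variant
    segregation triage, and a synthetic-cohort generator with planted QC
    defects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
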