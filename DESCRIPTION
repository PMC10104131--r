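Package: agtlink
Title: Linked AGT Variants, MicroRNA Duplex Energetics and Blood-Pressure
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for the two tightly linked angiotensinogen
    (AGT) variants rs699 A>G and rs5051 C>T.  Computes microRNA:mRNA duplex
    minimum free energies by intermolecular nearest-neighbor dynamic
    programming with a scrambled-target null and a perfect-match bound,
    expressing a variant's effect as a percent of the plausible binding
    range; estimates two-locus haplotype frequencies from unphased
    genotypes by EM, with linkage-disequilibrium statistics and
    Hardy-Weinberg expected combined-genotype frequencies; encodes
    subjects into the nine ordinal combined-genotype groups and fits
    covariate-adjusted linear and logistic blood-pressure models with
    stratified and z-scaled summaries; provides delta-delta-Ct qPCR
    fold-change statistics; and simulates seeded biobank-style cohorts so
    the whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
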