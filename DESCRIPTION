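Package: hetsim
Title: Heterosis, Inbreeding Depression, and Pedigree Forensics in Clonal Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantitative-genetic analysis of heterosis and
    inbreeding in clonally propagated hybrid crops genotyped with pseudo-diploid
    SNP arrays. Provides a breeding-population simulator (divergent founder
    groups, biparental F1 and S1 progeny, directional dominance, genetic load,
    multi-year randomized complete block trials), per-individual heterozygosity
    and inbreeding metrics, effective population size from heterozygosity decay,
    additive and dominance genomic relationship matrices, duo and trio genotypic
    transgression ratios for parentage verification, REML variance components and
    estimated marginal means for clonal trials, mid-/best-/worst-parent heterosis
    contrasts and their classification, directional-dominance kernel mixed models
    with a homozygosity covariate, a kinship-corrected marker scan, and
    single-locus generation-means theory for heterosis decay under fixation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    yaml
Config/testthat/edition: 3
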