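Package: dbsmix
Title: Single-Allele Deep Bisulfite Sequencing Simulation and Germ-Cell
    Mixture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of targeted deep bisulfite sequencing
    (DBS) amplicons at single-allele resolution. Generates synthetic
    bisulfite amplicon reads for cohorts of germ-cell/somatic-cell mixtures
    with known ground truth (imprinted differentially methylated regions,
    germ-cell marker promoters, the XIST CpG island, incomplete conversion,
    sequencing error, injected imprinting epimutations); calls per-read CpG
    methylation patterns via bisulfite-aware pairwise alignment with
    conversion-rate quality filtering; gates germ-cell fractions on marker
    purity, estimates the germ-cell proportion of a sample from unmethylated
    read counts with bootstrap uncertainty, models the mixture-driven
    methylation shift expected at imprinted loci and flags deviations from
    it; and compares group methylation levels by ANOVA with Holm-corrected
    pairwise t tests and letter-coded significance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
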