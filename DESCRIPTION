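Package: insulaR
Title: Runs of Homozygosity, Identity by Descent, and Population Insularity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying population insularity and consanguinity from
    diploid genotype panels: PLINK-style sliding-window detection of runs of
    homozygosity (ROH) and the F_ROH inbreeding coefficient; pedigree
    gene-dropping simulation of consanguinity null distributions and
    Mahalanobis classification of query genomes; maximum-likelihood effective
    population size from the 4-20 cM ROH length spectrum with
    profile-likelihood confidence intervals; LOD-score detection of identity
    by descent (IBD) segments on unphased genotypes with KING-robust kinship
    filtering, within/between-site sharing summaries and PCA of the total-IBD
    matrix; and a Wright-Fisher forward simulator with ancestry tracking that
    generates analysis-ready synthetic panels with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
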