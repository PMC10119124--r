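Package: codivkit
Title: Host-Symbiont Co-Diversification Analysis from Metagenomic Variant Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing co-diversification between a vertically
    transmitted bacterial symbiont and its host from metagenomic data.
    Profiles single-nucleotide variants (SNVs) of a dominant symbiont
    across host metagenomes as departure-from-consensus values, derives
    codon-level variants (SCVs), per-gene pN/pS selection statistics and
    single amino-acid variants (SAAVs) scored with BLOSUM62, infers host
    population structure from genotype likelihoods by covariance PCA,
    and tests host-symbiont congruence with the global ParaFit
    permutation statistic on Cailliez-corrected principal coordinates.
    A synthetic hologenome generator with full ground truth (two
    diverged host lineages, lineage-diagnostic symbiont SNVs, tunable
    horizontal transmission) makes the whole chain testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    yaml,
    mclust,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
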