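Package: qgscan
Title: Quantitative-Genetics Scans for Penetrance Traits in Inbred Nematode Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mixed-model genome-wide association with identity-by-state
    kinship and permutation-based false-discovery control, interval mapping
    for selfed recombinant inbred lines (hidden Markov genotype
    probabilities, EM likelihood scan, permutation thresholds and 1.5-LOD
    support intervals), phylogenetic-signal estimation (Pagel's lambda) on
    neighbor-joining trees from SNP distances, and a cross-trait reciprocal
    allelic-effect analysis with LD pruning and outlier control. Includes a
    synthetic-data generator for structured homozygous isolate panels,
    biparental recombinant inbred lines, and binomially sampled penetrance
    phenotypes, so that every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    ape,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
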