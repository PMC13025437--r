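Package: phylodem
Title: Single-Locus Phylogeography and Demographic Inference from mtDNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-locus mitochondrial phylogeography of
    geographically structured populations: haplotype collapsing and
    frequency-table bookkeeping, diversity summaries (segregating sites,
    haplotype and nucleotide diversity, mean pairwise differences),
    neutrality tests (Tajima's D, Fu and Li's D and D*, Fu's Fs,
    Ramos-Onsins and Rozas's R2) with coalescent-simulation p-values,
    sudden-expansion mismatch-distribution fitting (tau, theta0, theta1,
    SSD, Harpending's raggedness) with parametric-bootstrap uncertainty,
    and two-population isolation-with-migration divergence-time estimation
    by Markov chain Monte Carlo under an HKY substitution model. Includes
    a coalescent simulator (constant size, stepwise expansion, population
    split with migration) with HKY sequence evolution for power studies
    and significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
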