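Package: spokdrive
Title: Meiotic Drive by Spok Spore-Killer Genes in Podospora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tetrad-level simulation and analysis of spore killing by the Spok
    gene family in Podospora anserina and relatives. Simulates meiosis with a
    Poisson crossover process (first- versus second-division segregation),
    dikaryotic spore packaging, and a multi-locus killer/resistance calculus
    with epistasis and incomplete penetrance; classifies pairwise killer
    interactions (mutual killing, mutual resistance, dominance) with the
    F1-backcross design and assembles the emergent Psk killing hierarchy.
    Includes estimators for ascus-count data (spore-killing percentage,
    trinomial maximum-likelihood estimation of FDS frequency and penetrance),
    recurrent-backcross introgression and pooled-progeny allele-frequency
    simulators, and sliding-window sequence-diversity statistics for
    multi-FASTA alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
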