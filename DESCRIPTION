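Package: endosym
Title: Detection, Separation and Comparative Genomics of Intracellular
    Endosymbionts from Host Genome Data
Version: 0.1.0
Authors@R:
    person("endosym", "developers", email = "endosym@example.org",
           role = c("aut", "cre"))
Description: Tools for mining endosymbiont (e.g. Wolbachia) genomes from
    host whole-genome sequencing projects: SSU rRNA marker screening with
    consensus taxonomy, separation of endosymbiont reads and contigs from
    host sequence with nuclear-insertion (NUWT) filtering, origin-anchored
    genome normalisation with GC skew index, fragment-based average
    nucleotide identity and rearrangement breakpoint statistics, pangenome
    rarefaction by addition-order permutation, gap-tolerant WO-prophage
    region detection with module completeness calls, CifA/CifB
    toxin-antitoxin pair and biotin operon calling, distance-based
    phylogenetics and phylogenetic generalised least squares under a
    Brownian model. Includes a synthetic strain-set generator with planted
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
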