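Package: polyrate
Title: Subgenome Evolution Analyses for Allopolyploid Genomes
Version: 0.1.0
Authors@R: person("Polyrate", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tested, reusable implementations of the comparative analyses
    used to study subgenome evolution in allopolyploid plants such as
    cotton: pairwise divergence primitives (gap-aware p-distance,
    Jukes-Cantor correction, Nei-Gojobori Ka/Ks), relative-rate inference
    between homoeologous subgenomes with Wilcoxon signed-rank and
    chi-square machinery, molecular-clock dating of species splits and LTR
    retrotransposon insertions (T = Ks/2r), k-mer spectrum and TE-cluster
    genome composition comparisons, weighted-parsimony gene gain/loss
    mapping, and recombination-landscape analysis (D'-based haplotype
    blocks, Marey-map rates, methylation and chromatin-contact
    correlations). A synthetic-data module generates every input with
    planted ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
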