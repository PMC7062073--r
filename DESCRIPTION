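Package: mitoskew
Title: Mitogenome Architecture, Strand-Asymmetry Skews and Compositional
    Long-Branch Attraction
Version: 0.1.0
Authors@R:
    person("Mitoskew", "Developers", email = "mitoskew@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of compact circular
    mitochondrial genomes: intergenic spacer/overlap and non-coding
    region statistics, circular gene-order extraction and breakpoint
    distances, AT/GC skew profiling at genome, strand, gene and
    codon-position resolution with strand-asymmetry pattern
    classification, and scanning of non-coding regions for residual
    tRNA anticodon hairpins.  A synthetic-data wing simulates skewed
    mitogenomes and multi-taxon alignments with lineage-specific
    compositional convergence, and a seeded experiment quantifies the
    resulting long-branch-attraction artefact under different distance
    methods (p-distance versus LogDet) and outgroup strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
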