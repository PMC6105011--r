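Package: ptmevoscan
Title: Evolutionary Conservation of Post-Translational Modification Sites
    in Ordered and Disordered Protein Regions
Version: 0.1.0
Authors@R:
    person("ptmevoscan", "developers", email = "ptmevoscan@example.org",
           role = c("aut", "cre"))
Description: Annotates human protein residues as ordered, disordered or
    unclassified (with folding-on-binding regions, homopeptides, a
    compositional-bias prion-like call and a histone flag), builds
    reciprocal-best-hit ortholog maps from BLAST-style tabular hits,
    calls completely conserved and newly emerged residues across a
    strictly nested hierarchy of taxonomic clades from per-family
    multiple sequence alignments (optionally masked by per-column
    alignment-quality scores and with residue-class substitution
    allowances), and tests enrichment and depletion of
    methylation/acetylation/ubiquitination sites with exact
    hypergeometric tail probabilities under Bonferroni correction.
    Includes a deterministic, truth-labelled synthetic data generator
    emulating the nested-clade structure of a multi-proteome study, and
    a subcommand pipeline that runs the full analysis end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
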