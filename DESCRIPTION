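Package: cambdscan
Title: Screening Single-Nucleotide-Feasible Substitutions in Calmodulin-Binding Domains of Plasma Membrane Calcium Pumps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to delimit the C-terminal calmodulin-binding domain
    (CaMBD) of plasma membrane Ca2+-ATPase (PMCA) isoforms by motif
    scanning, score per-position amino-acid and per-codon nucleotide
    conservation, compute a weighted mutual-information covariation matrix
    with hierarchical clustering over the aligned 18-residue window,
    enumerate amino-acid substitutions reachable by a single nucleotide
    change at a chosen codon position, summarize structure-model confidence
    replicates (ipTM) with Student-t confidence intervals alongside Kabsch
    RMSD and backbone-dihedral quality checks, classify binding free-energy
    changes against method-specific cutoffs, and filter gene-disease
    association tables by score, association type and polygenicity. Seeded
    synthetic generators emulate every external input so the full workflow
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr,
    optparse
Config/testthat/edition: 3
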