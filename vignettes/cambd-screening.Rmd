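---
title: "Screening CaMBD substitutions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening CaMBD substitutions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cambdscan)
```

This vignette documents the models, parameter choices and numerical
conventions behind `cambdscan`, and what the packaged tests do and do
not establish about real data.

## The screening model

PMCA pumps are autoinhibited until Ca²⁺-loaded calmodulin engages the
C-terminal CaMBD, an amphipathic helix recognized through hydrophobic
anchors. In the 1–18 window convention used here, position 1 is the
tryptophan of the 1-5-8-14 anchor motif and position 18 the
phenylalanine that closes it (PMCA4b residues 1093 and 1110). The
package screens candidate missense substitutions in this window by
combining independent evidence layers: sequence conservation,
covariation, nucleotide-level mutational accessibility, model
confidence of predicted CaM–CaMBD complexes, and binding-energy
changes. Each layer is a separate module with file-based inputs, so any
layer can be recomputed or replaced without touching the others.

## Motif delimitation

Windows are found by an ungapped sliding-identity scan against the C28
reference peptide; the window anchor is the W aligned to C28 position 8.

* `min_identity` (default **0.6**) — fraction of matching residues
  required for a scan hit. Cross-isoform windows differ at up to 6 of
  18 motif positions while the C28 flanks (`LRRGQIL`, `HSS`) are nearly
  invariant, so true hits score well above 0.6 while random 28-mer
  background stays far below it. Equal-identity ties resolve to the
  leftmost window, which makes results order-independent.
* `strict_anchors` (default `"warn"`) — W1/F18 enforcement is advisory
  rather than fatal because orthologous windows can substitute anchors
  while remaining genuine CaMBDs.
* Redundancy collapse merges windows with *identical* 18-residue
  strings only; near-identical windows stay separate. A merged group
  keeps its first member's codons as representative — groups may mix
  synonymous codons (e.g. gtc vs gtg at position 14 inside
  PMCA2a_2b_3b), and downstream codon-level analysis of a group refers
  to that representative. Group labels print the first member in full
  and later members from their first digit (`PMCA2a_2b_3b`), which
  keeps labels short and reproducible from input order.

## Conservation and covariation

Nucleotide conservation is reported as 0–3 "stars" per codon position:
the number of intra-codon bases identical across all isoforms. This is
deliberately an exact, alignment-free statistic over the already
delimited windows.

Sequence weighting uses the Henikoff position-based scheme: in each
column every symbol type shares unit weight equally among the rows
carrying it, and a row's weight is its mean over columns, normalized to
sum to one. Gaps count as a symbol type for weighting. The covariation
hook also accepts externally supplied weights (e.g. derived from a
phylogeny) so that tree-based weighting can be swapped in without
changing the contract.

Covariation between columns *i* and *j* is mutual information over
weighted joint symbol frequencies, in bits, normalized by
`min(H(i), H(j))` so scores land in \[0, 1\] and an invariant column
scores zero by definition. Rows with a gap in either column are dropped
from that pair's counts and the remaining weights renormalized —
treating a gap as a 21st symbol would manufacture covariation from
shared indels. The pseudocount default is **0** so that small
alignments are exact against direct joint counting; a positive value is
available for larger, sparser alignments. The diagonal is `NA`: it is
per-column variability, not covariation. Clustering is average-linkage
agglomeration on `1 − score`, and the dendrogram exports to Newick.

## Codon feasibility

Any codon has exactly nine single-nucleotide neighbors, three per codon
position. The module defaults to editing the **second** base: the
middle position is the most determinative of amino-acid identity, so
second-position edits are the canonical route to missense variants,
while third-position edits are frequently synonymous. The packaged
substitution plan maps window positions 5, 6, 8, 14 and 18 to their
second-position targets, realizing L5R, N6I, I8T, V14E/D and F18S; the
choice among alternative second-position outcomes at a position is
configuration, not algorithm, because no selection rule beyond the plan
itself is defined. A realized edit must differ from the group's codon
at the configured position and nowhere else; unreachable plan entries
are reported rather than silently skipped. Stop gains are tracked as
`nonsense` and never form a substitution class.

## Model confidence and structural QC

Replicate ipTM scores (five models per complex by convention) are
summarized as `mean ± t·s/√n` with the Student-t quantile at
`(1 + level)/2` on `n − 1` degrees of freedom, default level **0.95**.
Display output rounds both bounds to two decimals and trims a trailing
zero (`[0.64-0.7]`); raw bounds are always retained in the returned
object, and rounding is display-only. Best-model selection is the ipTM
argmax with lowest-index tie-breaking.

RMSD uses the Kabsch algorithm: centroid removal, SVD of the
cross-covariance, and a determinant correction that disallows
reflections. Coordinate data frames are matched by
`(chain, residue number, atom name)` with a Cα default selection;
matching is explicit rather than order-based so partial models compare
correctly.

Backbone φ/ψ torsions follow the IUPAC sign convention (validated
against an independent torsion implementation); termini yield undefined
angles that are excluded from the favored-fraction denominator. The
favored-region map is a set of four documented rectangular boxes —
α (φ −160…−30, ψ −90…45), β (φ −180…−45, ψ 90…180 plus the ψ
wrap-around −180…−150) and left-handed α (φ 30…90, ψ −20…80). This is
a coarse QC statistic, not a PROCHECK-calibrated density: it
classifies ideal secondary structure correctly and flags gross backbone
problems, and should not be over-interpreted near region edges.

## Binding energetics

`ΔΔG = ΔG_substituted − ΔG_wild-type`, positive meaning weaker binding.
Classification cutoffs are method-specific: 1.7 kcal/mol for
FoldX-style estimates (twice the method's reported 0.85 kcal/mol error)
and 1.5 kcal/mol for MutaBind2-style estimates (the server's
meaningful-effect criterion). A value exactly at the cutoff is
*within error*: the grid contains 1.72, so the boundary convention is
observable — effects require strictly exceeding the cutoff. MutaBind2
values are taken with their native sign convention (positive =
decreased affinity) and are never flipped on ingest. Wild-type pairing
for ΔΔG is explicit: the packaged literature table carries both the
published ΔΔG and the underlying energies, and for the PMCA3b G→D row
the two disagree (9.29 published vs 11.27 from the printed energies —
the wild-type complex used for that row is ambiguous). Both numbers are
carried; only the rows whose arithmetic is internally consistent are
used as checked values.

## Disease context

Predictor scores categorize as benign (<0.2), possibly damaging
(0.2–0.85) and probably damaging (≥0.85); the published category ranges
overlap at 0.85, resolved here as half-open intervals with 0.85
probably damaging. Gene–disease association records filter by a
minimum association score (0.3 general, 0.5 high-confidence) and by
association type (causal-mutation and genetic-variation classes by
default). Polygenicity is the number of genes linked to a disease:
1 monogenic, 2 oligogenic, ≥3 polygenic, stratified at ≤30 vs >30 genes
as an empirical visualization split. Records pass through unmerged —
no deduplication rule across genes is applied, because none is defined.
All disease and expression data are ingested from user-supplied CSV
exports; live database queries are out of scope to keep the package
hermetic and version-stable.

## Synthetic fixtures

The generators emulate the *statistical and file-format surface* the
workflow consumes, under the study's conditions:

* `gen_isoform_family` — 11 isoforms by default, each embedding the
  PMCA4b window inside the C28 flanking context and random flanks, with
  per-site divergence 0.1 at non-anchor positions (W1/F18 fixed) and a
  CDS built by seeded uniform synonymous reverse translation.
* `gen_iptm_replicates` — Gaussian replicates, default mean 0.65 and
  sd 0.03, matching the scale and spread of wild-type complex scores
  (means 0.52–0.74, interval widths mostly below 0.1), clamped to
  \[0, 1\].
* `gen_energy_tables` — ddG draws whose true class matches a planted
  effect mix exactly; the default mix (51 weakening, 5 strengthening,
  14 within-error per 70) mirrors the observed cohort proportions.
* `gen_gda_table` — association records spanning all polygenicity
  classes and both strata, with scores and types drawn uniformly.

Every generator is a pure function of `(seed, parameters)`, with
independent derived substreams per generator so adding one fixture does
not shift another. What passing tests show: the pipeline's logic —
delimitation, dedup, classification, filtering, interval construction —
recovers planted truths exactly and meets nominal statistical
guarantees (95% interval coverage within \[0.93, 0.97\] over 2,000
replicate sets of five). What they do not show: anything about real
AlphaFold geometry, force-field energetics, or curated database
content; the generators have no structural physics and no biological
covariance between layers.

## Problem sizes and numerical conventions

The test suite runs the exhaustive 64-codon × 9-neighbor synonymy
check, mutual-information oracle comparisons on alignments up to 6 × 6,
clustering oracle comparisons up to 7 columns, and the 2,000-set
coverage simulation; these sizes make the whole suite complete in well
under a minute while keeping every check either exhaustive or
statistically tight. Degenerate inputs are defined rather than left to
chance: zero-spread replicates give a zero-width interval at the mean;
collinear atoms give an `NA` torsion with a warning; all-gap columns,
empty FoldX files and out-of-range scores are errors. Dendrogram
merge-height ties are broken deterministically by `stats::hclust`;
scan ties go to the leftmost window.

## Known limitations

* The mutual-information weighting is Henikoff position-based; it
  approximates, but is not identical to, server-side "phylogeny
  weighted" schemes whose exact definition is unpublished. Cluster
  *membership* on real ortholog alignments should be interpreted
  qualitatively.
* The favored-region boxes are coarse rectangles, suitable for QC of
  clearly helical interface models, not for publication-grade
  stereochemistry validation.
* Windows are compared ungapped; the package does not align full-length
  proteins and assumes the CaMBD is contiguous in sequence.
* ΔΔG classification inherits whatever systematic error the upstream
  energy method carries; the cutoffs bound random error only.
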