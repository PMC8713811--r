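---
title: "Methods: signature-based classification of MHC-like chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature-based classification of MHC-like chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wcategory)
```

## The problem

MHC class I and class II molecules share four extracellular domains — two
membrane-distal domains forming the groove superstructure and two
membrane-proximal, Ig-like C1-set domains — but combine them differently:
class I as a three-domain heavy chain (α1, α2, α3) plus the free Ig domain
β2-microglobulin (β2m), class II as two two-domain chains (α = α1+α2,
β = β1+β2), each with its own CP/TM/CY region. The W-category is a third,
ancient group: chains with class II architecture (an α-chain WA and a
β-chain WB) whose sequences nevertheless carry class I diagnostic residues,
most strikingly at the three interdomain interfaces of a class I molecule.
This package operationalizes that comparison: a declarative residue-signature
schema, a domain mapper, a chain classifier, an interface typer, a
distance/NJ/bootstrap stage for the WAα2 + β2m clustering question,
conservation profiling, and a head-to-head gene-pair detector, all testable
on synthetic data with known ground truth.

## Position frames and the signature schema

All diagnostic residues are addressed in *frame coordinates*: canonical
column numbers on a fixed consensus for each domain family (`IG_C1`, 94
columns; `DISTAL_A1TYPE`, 86; `DISTAL_A2TYPE`, 92; `TM`, 24). Frame
numbering is 1-based. The consensus backbones are fixed arbitrary
sequences shipped with the package — they are coordinate scaffolds, not
reconstructions of any real gene — generated once under a frozen seed with
two constraints: the Ig frame carries the IgSF-invariant features
(tryptophan at column 37, cysteines at 21 and 86), and the consensus
residue at every signature column differs from every class's diagnostic
residues, so that a background chain never matches a signature by
construction.

The default schema encodes only the residues that the main comparative
argument rests on:

```{r}
schema <- default_schema()
query_signatures(schema, "IG_C1", 61)
```

Ig position 61 separates β2m/WAα2 (W) from class I α3/WBβ2 (G) and from
conventional class IIB (invariant W); position 37 holds the IgSF-core
tryptophan that β2m (L37) and WAα2 (F/L37) have replaced; P57 (β-side) and
Y8 (α-side) form the conserved α3/β2m hydrogen bond; L55 and F/(Y)57
complete the β2m-like set; the distal tier contributes V30 (α1-type frame)
and Q6, A32, G35, D37 (α2-type frame). Richer residue sets can be supplied
through a user schema file (`load_schema()`); the schema dialect is plain
JSON with `frames`, `signatures`, `indel_regions` and
`tm_glycine_patterns` keys, round-tripped exactly by `write_schema()`.

Two schema components are deliberately marked `provisional`: the exact TM
glycine positions and the coordinates of the three distal indel-signature
regions. Both features are real discriminators in the source data
(chain-type-specific TM glycines; class I/class II length disparity at
three distal regions), but their column-exact placements are not published
at main-text resolution, so the defaults are package conventions that users
can override.

## Weights

Interface-role signatures carry weight 2.0 and all others 1.0, reflecting
that interface residues are the most pronounced shared features. Q6 is the
one exception at weight 0.5, because it is also conserved to some extent in
class II and therefore discriminates weakly. TM-glycine and indel-region
evidence enter at weight 1 each. These weights are calibration choices, not
published constants.

## Domain mapping

`map_to_frame()` aligns a sequence globally to a frame consensus
(BLOSUM62, affine gaps: a gap of length *k* costs 10 + *k*), and reports a
frame-column → query-index map plus a score normalized by the consensus
self-alignment (clamped to [0, 1]). `segment_chain()` finds the Ig domain
with a pattern-global/query-local alignment, walks upstream for at most two
distal domains (taking the downstream-most confident hit each round, so a
class I α1+α2 tandem is resolved right-to-left), and scans downstream of
the Ig domain for a membrane anchor with a 19-residue Kyte–Doolittle
window at mean hydropathy ≥ 1.6. Signal peptides are not modeled; synthetic
chains are generated without them.

The confident-mapping threshold is a normalized score of 0.35, calibrated
so that fewer than 1% of length-matched shuffles of a frame consensus pass
(in the shipped calibration, shuffled consensi score 0 after clamping, so
the margin is wide). Domain boundaries are defined as the extent of the
frame mapping; where real exon borders are unknown this is a convention,
not an inference.

Numerical conventions: query coordinates are 0-based half-open, frame
columns 1-based (matching the alignment numbering used in the field);
alignment ties are resolved deterministically by the aligner; the TM
interval is the union of all windows passing the threshold.

## Classification

For each class, the score is the matched signature weight over the weight
readable at non-gap columns — gapped columns are excluded from numerator
and denominator alike, so missing data neither helps nor hurts. Classes
with zero readable weight are flagged and scored 0. Architecture gates the
label: three extracellular domains admit only the class I heavy chain, one
admits only β2m, two admit the four class II / W-category chains. TM
glycine patterns are matched by the *spacing* between glycines inside the
detected anchor (α-type positions 8/12 → spacing 4; β-type 9/15 → spacing
6) rather than by absolute columns, because the hydropathy scan yields an
interval, not a column map. The label is the arg-max class when its margin
over the runner-up is at least τ = 0.15 (when gating leaves one candidate,
the margin is the score itself), else `UNKNOWN`. τ was chosen so that
planted classes separate cleanly at a 5% mutation rate while signature-free
random chains stay `UNKNOWN` at ≥ 95%; both properties are exercised in the
test suite.

## Interface typing

`evaluate_interfaces()` reads a fixed residue panel per interface:
α1α2/β2m from the α-chain Ig residues L55, F/Y57, W61 plus the distal
residues V30 (α1-type frame) and Q6/A32/G35/D37 (α2-type frame, read from
whichever chain carries that frame); α1α2/α3 from the β-chain Ig position
61 alone (G → class I-like, W → the class II diagnostic); α3/β2m from the
β-chain P57 and α-chain Y8. The verdict rule — `CLASS_I_TYPE` if at least
2/3 of the weighted class I signatures match and the class II diagnostic is
absent; `CLASS_II_TYPE` if the diagnostic matches; otherwise `AMBIGUOUS` —
is this package's quantitative construction; the source comparison is
qualitative. The report always enumerates exactly the three interfaces.

## Phylogenetics

`pdistance()` computes the proportion of differing sites over mutually
ungapped columns (optionally Poisson-corrected, −ln(1−p)). `nj_tree()` is
a Saitou–Nei neighbor-joining implementation with a deterministic
tie-break (lowest active-node index pair) and negative branch estimates
clamped to zero; it is written in-package so that replicate runs are
bit-reproducible, and is checked in the tests against both an independent
NJ implementation and an exhaustive minimum-evolution search with OLS
branch lengths. NJ stands in for maximum likelihood throughout: the
clustering question this package asks is method-robust, and ML estimation
is out of scope. `bootstrap_support()` resamples columns with replacement
(Mersenne-Twister, seed recorded in the output), tallies non-trivial
bipartitions, and `clade_support()` answers the WAα2 + β2m question as the
support of the bipartition separating the designated taxa; trivial
bipartitions return 100 by definition. Outgroup rooting is display-only —
supports are computed on unrooted bipartitions.

## Conservation profiling

`column_conservation()` reports per-column modal residue, modal fraction
and Shannon entropy (bits) under pairwise deletion; all-gap columns are
flagged. `compare_profiles()` correlates modal fractions over a designated
position set (e.g. groove positions). The groove position list ships empty
— the published list is supplementary-only — so it is a required user
input; no statistical test of profile resemblance is attempted because the
underlying claim is qualitative.

## Genomic pairs

Class II-type exon structure is matched by length windows: at least three
coding exons whose first two (in transcription order) fall in the
distal-exon (250–278 bp) and Ig-exon (280–300 bp) windows; a class I gene
needs two distal-length exons before the Ig-length exon and at least four
exons. Head-to-head pairs are adjacent genes on opposite strands with 5′
ends facing — operationally, the minus-strand gene upstream of the
plus-strand gene in contig coordinates — within `max_distance` (default
20 kb; the source figures show ~1–2 kb gaps but state no threshold),
matched greedily by smallest gap with each gene in at most one pair.
Annotation strand is trusted; no transcript evidence is required. The pair
finder reports candidates by position only; which gene encodes the α- vs
β-chain is a sequence-classification question, not a geometry question.

## Synthetic data: what it emulates, and what it does not

`make_chain()` concatenates the frame consensi of a class's layout, plants
the class's diagnostic residues (sampling uniformly inside multi-residue
sets such as F/Y57), deletes the indel regions the class lacks, plants the
TM glycines, and mutates the remaining positions at rate μ (uniform
replacement among the other 19 residues; IgSF-invariant columns are
protected). Defaults are μ = 0 — the noise-free condition in which the
planted chains *are* the signature definitions — with μ a dial for
robustness experiments. `make_alignment_set()` evolves the Ig consensus
along a tree under a Poisson uniform-replacement model (substitution
probability 1−exp(−b) on a branch of length b) and overwrites five
diagnostic columns (defaults: the β2m-signature columns 8/37/55/57/61 with
Y/L/L/F/W) on the planted clade's leaves — shared derived states on the
clade stem. `planted_clade_tree()` supplies a 12-taxon default tree (a
4-taxon planted clade beside 8 background taxa with branch lengths drawn
from U(0.05, 0.25)), sizes chosen to resemble a small cross-species Ig
domain panel. `make_locus_gff()` lays out facing gene pairs (2 kb
intergenic gap) and decoys in 30 kb-separated blocks.

The generator emulates the *statistical structure* of the comparison —
class-diagnostic residues on otherwise exchangeable backbones, a clade
defined by shared derived columns, divergent gene orientation — and none of
the biology it does not need: no real sequence composition, no signal
peptides, no rate heterogeneity, no realistic branch lengths or intron
sizes. Tests passing on these data show that the machinery measures what it
claims to measure; they do not validate recovery rates on real genomes.

## Problem sizes and determinism

The shipped tests and the acceptance script use 100 chains per class for
the noise-free recovery check, 10 per class per seed across μ ∈
{0, 0.02, 0.05, 0.1} for the monotonicity check, 50 additive matrices for
the NJ/minimum-evolution equivalence, 20 simulations × 100 bootstrap
replicates for planted-clade support, and 20 simulated loci for pair
recovery — sizes at which every stochastic check is comfortably inside its
binomial error band while the whole suite stays quick. Every stochastic
step takes an explicit seed; identical configurations give byte-identical
outputs, and the pipeline report records seed, generator and parameters.

## Known limitations

- The default schema carries only the main-text residue set; full red/blue
  residue inventories belong in a user schema.
- Indel-region coordinates and TM glycine positions are provisional
  conventions (see above).
- Domain boundaries equal frame-mapping extents; no HMM, no secondary
  structure, no signal-peptide model.
- No ML/Bayesian trees, no rate heterogeneity, no DNA-level distances.
- The interface verdict thresholds (2/3 weighted majority) quantify a
  qualitative published comparison and should be read as such.
- Allelic polymorphism and peptide-binding capacity are out of scope.
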