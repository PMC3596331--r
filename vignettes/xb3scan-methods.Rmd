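---
title: "Methods: domain scanning, classification and expression calls in xb3scan"
author: "xb3scan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain scanning, classification and expression calls in xb3scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xb3scan)
```

## The biological problem

XB3-like proteins are plant E3-ubiquitin-ligase-type proteins defined by two
structural features: an array of two to seven tandem 33-residue ankyrin (ANK)
repeats, and a single C3HC4-type RING finger.  The RING's eight metal ligands
(seven Cys and one His, in the order C,C,C,H,C,C,C,C) coordinate two zinc ions
in a cross-brace arrangement — ligand pairs 1&3 bind one zinc, 2&4 the other —
which rigidly constrains some inter-ligand spacings while leaving others free
to vary.  Within the XB3-like family those free spacings, and a handful of
conserved residues flanking the ligands, separate the family into three
phylogenetic groups; the ANK repeat count separates it into six size classes.

`xb3scan` implements the whole desk-side analysis of such a family:
domain detection, group and class assignment, physicochemical annotation,
neighbour-joining phylogenetics, and qPCR expression calls, together with
synthetic-data generators that provide exact ground truth for every stage.

## RING detection model

A domain is accepted when eight positions match the ligand pattern under
these spacing constraints (counts are residues *strictly between* the two
named ligands; intervening ligands count among them):

| quantity | constraint | role |
|---|---|---|
| d12, d78 | exactly 2 | cross-brace invariants |
| d23 | exactly 11 | family-specific constant |
| d36 | exactly 7 (includes L4 and L5) | cross-brace invariant |
| L3–L4 | 1–3, L4–L5: 2–3 | canonical C3HC4 sub-spacing |
| d67 | 11–24 (union of the group windows) | group diagnostic |

The "between, counting intervening ligands" reading of d36 is forced by
arithmetic: with the canonical sub-spacings the strictly-between count is
1+1+2+1+2 = 7, which is the family constant; excluding L4/L5 could never
reach 7.  Three conserved signature residues (Pro right after L7, Arg right
after L8, Val/Ile right before L2) are required in `strict` mode and recorded
as flags in `tolerant` mode, because rare natural family members deviate in
exactly one of them; `tolerant` mode finds those while keeping the deviation
visible.  Multiple accepted domains are resolved left-to-right,
leftmost-start first; the family pipeline classifies a protein by its
leftmost domain and reports all.

Group assignment is a decision list: d67 = 11 is uniquely group III, 19–20
uniquely group I, 24 uniquely group II; in the 21–23 overlap the residue
before L8 (Leu = I, Phe = II) decides, and anything unresolved is
`unassigned` with a rule trace rather than a guess.

## ANK detection model

Detection scores every 33-column window against a packaged consensus (after
the designed ankyrin consensus of Mosavi and colleagues, with degenerate
positions instantiated; it contains no Cys, so ANK arrays cannot mimic RING
ligands) using BLOSUM62.  Because the BLOSUM62 diagonal dominates every row,
the consensus' self-score (164) is the maximum achievable window score.
Windows at or above the threshold are accepted greedily by descending score,
discarding overlaps — transparent, and exact on tandem arrays because a
shifted window always scores far below an aligned one.

The default threshold of 80 was fixed once by `calibrate_threshold()` at a
target false-positive rate of zero: repeats carrying up to 4 point mutations
cannot score below 121 (worst-case drop per mutation bounded by the BLOSUM62
row ranges), while the best window in 1000 random length-200 background
sequences scored 24.  80 sits near the centre of that wide gap, so repeat
counting is insensitive to the exact value over tens of score units.
Counts map to classes A–F = 2–7 repeats; 0, 1 or more than 7 repeats are
`unclassified` (membership itself never caps the count: the 2–7 range is
observational, not a filter).

## Membership rule

A protein is an XB3-like family member iff it has at least 2 accepted ANK
repeats and at least one accepted C3HC4 RING.  Rejections carry the failed
rule in a `reason` column; per-record failures (for instance a non-canonical
residue) are isolated and reported, never fatal to the run.

## Physicochemical annotation

Molecular weight is the sum of packaged *average* residue masses plus one
water (18.0153 Da), matching the convention of the common proteomics servers.
The isoelectric point is the unique root of the Henderson–Hasselbalch net
charge over the termini and the D, E, C, Y, H, K, R side chains with the
packaged Bjellqvist pK set (generic termini).  Net charge is strictly
decreasing in pH, so bisection on [0, 14] converges to the unique root; we
bisect to a 1e-6 bracket (well past the 1e-4 documented tolerance) so the
charge at the returned point is always below 1e-3 in magnitude.  The pK
variant used by any given server version is not knowable in general; the
packaged table is versioned in `inst/extdata/` so results are reproducible
against a stated reference.

## Phylogeny

Trees are built the way protein-family surveys traditionally build them:
p-distance (fraction of differing sites) on gap-free columns after *complete
deletion* (every column containing a gap in any row is removed), then
neighbour joining with the Saitou–Nei Q-criterion, then bootstrap over
column resampling.  Conventions that the literature leaves open are fixed
for determinism: Q-minimum ties break to the lowest index pair; negative
branch lengths are clamped to zero with the absorbed amount added to the
sibling edge; Newick output carries supports as internal node labels and
branch lengths with 6 decimals.  NJ is exact on additive matrices, which the
tests exploit: random additive matrices must be recovered to 1e-9 in path
lengths, and an independent NJ implementation (`ape::nj`) must agree on the
topology.  Alignment construction itself (ClustalX/MUSCLE-style heuristics)
is out of scope; the module ingests aligned FASTA, and the synthetic
generator emits already-aligned families.

## Expression analysis

Normalisation is delta-Ct per replicate: dCt = Ct(gene) − mean Ct(reference
genes) within the same condition and replicate; relative expression is
2^(−dCt), assuming 100% amplification efficiency (factor 2 per cycle; no
efficiency correction is applied).  Fold change between conditions is
2^(mean dCt(control) − mean dCt(test)), i.e. computed from mean dCt rather
than averaged per-replicate ratios (the two differ only by Jensen-gap terms
at qPCR noise levels; the mean-dCt form is the standard one).  P values come
from the classic equal-variance two-sided Student t on replicate dCt values;
zero-variance groups (possible only in noise-free synthetic data) short-cut
to the limit values 0 or 1.  Two decision rules are implemented exactly as
commonly practised for qPCR panels: *treatment response* = fold change above
1.2 (or below 1/1.2) with P < 0.05 against the control; *preferential
expression* = more than 2-fold higher with P < 0.05 against **every** other
tissue, a for-all reading that provably admits at most one winning tissue.
No multiple-testing correction is applied by default (matching common qPCR
practice); Benjamini–Hochberg adjusted P values are available as an opt-in
column.

## Synthetic data: what it emulates and what it does not

The generators produce ground truth by construction, validated at source:
every generator re-scans its own output and errors if the scanners do not
recover the recorded truth.

* `make_member()` concatenates a random N-flank, tandem mutated consensus
  repeats, a linker, and a group-consistent RING region.  Filler *inside*
  the RING region excludes C and H so the embedded ligand set is
  unambiguous; flanks and linkers draw uniformly from all 20 residues, so
  stray flank cysteines remain as legitimate hard cases.  Defaults: 5
  repeats (the modal class in real family surveys), 2 mutations per repeat,
  30-residue flanks, 25-residue linker, d67 uniform over the group window.
* `make_decoy()` covers the four failure modes the membership rule must
  reject: RING without repeats, a single repeat, a C3H2C3 zinc finger (His
  in the ligand-5 slot), and a shuffled member.
* `make_family()` evolves a root sequence down a known tree with per-site
  substitution probability 1 − exp(−rate × branch length), uniform over the
  19 alternatives, and **no indels** — alignment ground truth stays exact,
  at the cost of not exercising gap handling (complete deletion is tested
  separately on hand-built gapped alignments).
* `make_ct_table()` puts the reference gene at 20 cycles and targets at
  20 + 5 − effect, plus Gaussian replicate noise (default sd 0.1 cycles,
  a typical technical-replicate scatter).

Background composition is uniform over the 20 residues — real proteomes are
not, so passing tests demonstrate correctness of the rules and scanners, not
real-proteome false-positive rates; the calibration utility exists precisely
so a user can re-fix the ANK threshold against a composition of their
choosing.  All generators are pure functions of (spec, seed) and restore the
caller's RNG state.

## Problem sizes and numerical choices

The shipped tests run the scanners over a few hundred synthetic proteins
(3 groups × 50 seeds for group recovery; 6 repeat counts × 25 seeds for ANK
counting), compare the RING scanner against an exhaustive regex-based
enumeration on sequences up to 120 residues, check NJ on dozens of random
additive 6-taxon matrices, and simulate 2000 null qPCR genes for the type-I
error check — sizes chosen so the whole suite gives tight empirical bounds
in well under a minute per module.  Determinism conventions (tie-breaks,
clamping, fixed seeds) are stated above; degenerate inputs (empty cohorts,
all-gap alignments, constant replicates, sub-33-residue sequences) all have
defined, tested behaviour rather than incidental errors.

## Known limitations

* The packaged consensus/BLOSUM scanner is not a profile HMM; boundary
  refinement beyond the fixed 33-column window, and highly diverged repeats
  (more than ~12 mutations), are out of reach by design.
* Modified RING subtypes (RING-V, RING-D, RING-S/T, RING-G, RING-C2) are
  rejected, not classified.
* p-distance with complete deletion discards information relative to
  model-based distances; that is the point (it reproduces the conventional
  survey setting), not a recommendation.
* Real proteome screens additionally involve homology search against genome
  databases; that stage is external to this package, which starts from
  protein FASTA.
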