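---
title: "Identifying RNA functional determinants from structure and mutagenesis data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying RNA functional determinants from structure and mutagenesis data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mc3dqsar)
```

## The problem

Mutagenesis and growth or cleavage assays tell us *which* sequence variants
of an RNA motif are functional; crystallography tells us *where* the atoms
are, but usually only for one or two variants. `mc3dqsar` combines the two:
starting from a single high-resolution reference structure and a list of
active/inactive sequences, it asks which solvent-exposed base chemical
groups are (i) geometrically conserved across every active variant and
(ii) lost in at least one inactive variant. Those groups — individual
donors, acceptors and neutral carbons on the base edges — are the *activity
determinants*: the chemical surface an interacting partner (an elongation
factor, a catalytic metal, another strand) most plausibly reads out.

This vignette documents the model, its parameters, the numerical choices,
and what the synthetic test bed does and does not establish.

## Variant model building

Each variant's model "conserves the position and orientation of the bases"
of the reference: for every substituted position, an idealized nucleotide
template (standard ideal geometry, shipped as data) is rigid-body fitted
onto the existing base and its base atoms replace the old ones; sugar and
backbone atoms are untouched. The least-squares fit uses:

* **same-class substitutions** — all shared ring atoms (9 for purines, 6 for
  pyrimidines); residual RMSDs are in the 0.01 Å range, since ring
  geometries of the canonical bases are nearly identical;
* **purine↔pyrimidine substitutions** — the glycosidic nitrogen and its two
  ring neighbours, mapped N9→N1, C8→C6, C4→C2. The mapping is our choice:
  it anchors the new base at the same glycosidic attachment with the ring
  extending over the old ring's footprint, which is the minimal reading of
  "conserved position and orientation". Three atoms determine the rigid fit
  exactly; no other constraint is imposed.

No relaxation follows substitution. This is deliberate: the method's premise
is that naive grafting is informative on its own, and the clash detector
(below) flags the cases where it is not. Model building is deterministic —
the same seed and variant give bit-identical coordinates — which makes
profiles reproducible byte-for-byte.

Because substituted models inherit the seed's frame, training structures are
already mutually superposed. For externally built models, `superpose()`
provides a least-squares backbone fit (P, O5', C5', C4', C3', O3') into the
seed frame.

### Clash screening

`detect_clashes()` reports heavy-atom pairs from different residues closer
than 2.0 Å, excluding the bonded O3'–P linkage of consecutive residues. The
2.0 Å cutoff is our operationalization of a "serious" clash — roughly 1 Å
of van der Waals interpenetration for first-row atoms — chosen because
naive base grafting produces either near-contacts (> 2.5 Å, tolerable) or
deep overlaps (< 1.5 Å, irrecoverable), so the verdict is insensitive to
the exact value. Clashing models are flagged but still scored: a clash is
evidence about the variant (the substituted pair cannot adopt the reference
geometry), not a reason to drop it.

## Base chemistry

Roles are a fixed function of (base, atom): e.g. for guanine N1/N2 donors,
N3/O6/N7 acceptors, C2/C8 neutral. Glycosidic nitrogens and pure
ring-junction carbons carry no role and can never be determinants. The 2'
hydroxyl is protonated for the solvent-accessibility computation but carries
no role either: base-edge chemistry is the object of study, and backbone
groups would otherwise dominate every profile trivially (they are present in
all variants).

Direction vectors encode where an H-bond partner would sit, and are needed
because two groups with the same role at the same position can still point
into different half-spaces after a substitution. The conventions are
standard sp² stereochemistry, kept in one table:

* donors: one N→H unit vector per attached hydrogen (amino groups carry
  two);
* carbonyl oxygens: two in-plane lone pairs at ±60° from the C→O extension;
* ring-N acceptors: the in-plane external bisector of the two adjacent ring
  bonds;
* neutral C–H: the C→H direction (same external bisector);
* neutral carbons without hydrogens (guanine C2): the in-plane vector from
  the ring centroid through the atom. Such atoms can be determinants, so
  they must carry *some* direction for the dot-product term; the radial
  choice is the natural one and agrees with the bisector convention in the
  limit.

Hydrogens in input files are discarded and rebuilt with ideal geometry
(N–H 1.01 Å, C–H 1.08 Å, in-plane; O2'–H 0.96 Å along the C2'→O2'
extension, its torsion being irrelevant at the accuracy SASA needs), so
crystal structures, substituted models and synthetic fixtures are treated
identically.

## Solvent accessibility

`compute_sasa()` is a native Shrake–Rupley implementation: each atom's
expanded sphere (van der Waals radius + 1.4 Å probe) is sampled with a
deterministic Fibonacci lattice (default 960 points ≈ 0.13 Å² resolution at
nitrogen radius), and the free fraction is the area. Hydrogens both occlude
and carry area; a group's exposed area is heavy atom + attached hydrogens,
and the exposure threshold (0.25 Å², inclusive) is applied to *all*
structures uniformly — seed, training models and scored variants — as one
rule stated in the profile metadata.

Two implementation choices deserve note:

* **Rigid-body invariance.** The lattice is laid out in a canonical
  molecule-local frame (centroid plus covariance eigenvectors, signs fixed
  by third moments), so areas are invariant under rotation/translation of
  the whole structure to numerical precision rather than to sampling noise.
  The frame is degenerate only for pathologically symmetric point sets,
  which real nucleotides never are.
* **The threshold sits near sampling noise.** At 960 points, one lattice
  point is worth ~0.13 Å², half the 0.25 Å² threshold. Reports therefore
  flag groups within ±0.05 Å² of the threshold as borderline. The
  independent Monte-Carlo oracle (`mc_sasa_oracle`, rejection sampling with
  binomial standard errors) is used in the test suite to confirm the
  engine within 3% on random clusters; convergence tests compare 960
  against 10⁴ points.

The van der Waals set (C 1.70, N 1.55, O 1.52, P 1.80, H 1.20 Å) is a single
fixed published set recorded in every output artifact; swapping it is a
configuration change, not a code change.

## Profile construction and scoring

Potential determinants are the seed's exposed groups. The match score
between a determinant and a candidate group is 1.0 if roles agree (0
otherwise), divided by the squared inter-atomic distance when that distance
exceeds 1.0 Å (kept as-is below), times the best scalar product among the
two groups' direction vectors. Negative scalar products clamp to zero: an
anti-aligned direction is no match, and scores must stay in [0, 1]. With the
0.75 threshold, a perfectly aligned group may sit at most ~1.15 Å from the
determinant — the tolerance that lets a substituting atom (say a uracil O4
standing in for a lost guanine N7) be recognized, while anything on another
edge of the base scores below 0.2.

The candidate search deliberately spans *all* exposed groups of a model,
not just the same residue; substitution-compensation across neighbouring
positions is a real phenomenon the method is designed to capture.

A seed group is kept as a determinant iff its best match is ≥ 0.75 in every
positive and < 0.75 in at least one negative. The negative-side rule
("absent") is operationalized with the same threshold — the natural reading,
recorded in the profile metadata. With no negatives the determinant list is
empty (with a warning): nothing can be tied to loss of activity. The
profile is anchored on the seed's group positions; any positive example
could serve, so the seed is an explicit, named input.

Prediction applies **no** per-determinant threshold: the activity score of a
variant is the plain mean of best-match scores over determinants. Scoring a
structure in which every determinant self-matches returns exactly 1.0, and
on its own training set the construction guarantees actives at 1.0 and
inactives strictly below — the separation property the parameter defaults
(probe 1.4 Å, area 0.25 Å², match threshold 0.75, distance floor 1.0 Å)
were published with. `parameter_sweep()` re-derives this calibration
surface (areas 0–1 Å² in 0.25 steps, thresholds 0.05–0.95) for any data
set.

One boundary case: if a variant loses *every* group matching a determinant,
its per-determinant score is not exactly 0 — a same-role group elsewhere in
the model contributes a small residual (≤ 1/d² ≈ 0.02 at 7 Å). Exact zeros
occur only when no same-role group is exposed anywhere. This is a direct
consequence of the whole-model candidate search and is intended.

## The synthetic test bed

The fixture generators make the whole pipeline testable without downloads,
at desk scale (3–6 nucleotides, < 2 s per structure):

* `make_fixture()` places idealized whole-nucleotide templates on a flat
  ladder (9 Å spacing, clash-free, everything exposed) or a twisted stack.
  Burial is emulated by inert occluder pseudo-atoms (vdW 1.7 Å, no roles)
  caged around a target group at 2.0 Å radius, in directions not already
  self-occluded by bonded neighbours. The cage cleanly buries lone
  acceptors (N7, O6, O4); burying hydrogen-bearing groups can collaterally
  bury an adjacent narrowly-exposed ring nitrogen, so tests use the former.
* `make_planted_training_set()` constructs a seed plus positive/negative
  copies in which the determinant set is known *by construction*: planted
  exocyclic groups are deleted in negatives (round-robin), one non-planted
  control group is deleted in the first positive (so it fails the
  present-in-all-positives rule), and everything else is present everywhere
  (so it is filtered as uninformative). Deletion emulates what base
  substitution does to group inventories while keeping base rings intact.
  Positive-side jitter defaults to 0 — substitution over a common reference
  reproduces unchanged positions exactly, and this is what makes "actives
  score exactly 1.0" hold — and is capped at 0.3 Å translation / 15° base
  rotation, within which a preserved group's match stays ≥ cos 15° ≈ 0.97,
  far above 0.75.

Passing on this bed establishes that the filtering rules, the score
arithmetic, the SASA engine and the substitution machinery are correct and
deterministic. It does **not** establish performance on real crystal
structures: fixtures have no tertiary packing (burial is an artificial
cage), no non-canonical pairs, no experimental coordinate noise, and their
inter-residue spacing removes cross-residue compensation except where a test
constructs it. The crystal-structure case studies require the corresponding
PDB entries and variant tables as external inputs (`inst/extdata/reference/`).

## Degenerate inputs and tie-breaks

Alternate locations resolve to the highest-occupancy conformer; ties fall
back to altLoc order. Best-match ties break by smaller distance, then
(residue, atom) order, making reports deterministic. Incomplete base rings
are a hard error naming the residue; missing *exocyclic* atoms are legal
(they are how deletion scenarios and modified learning sets are expressed)
and simply remove the corresponding group and hydrogens. Empty structures,
unknown bases, malformed substitution tokens and residue/range mismatches
all fail fast with the offending record named.

## Known limitations

* Naive substitution cannot model local rearrangements; where a variant's
  true structure reorganizes (e.g. a pyrimidine:pyrimidine junction pair
  that repacks), scores computed on grafted models underestimate the
  variant, and only externally built models recover the published
  behaviour. The clash flag marks the cases where grafting is structurally
  impossible outright.
* Stacking, backbone conformation and electrostatics are outside the model;
  determinants are base-edge H-bonding chemistry only.
* The 0.25 Å² exposure threshold interacts with lattice resolution;
  borderline groups may differ from implementations using other dot
  densities (hence the borderline flag in reports).
* Modified nucleotides, protonated bases and tautomers are not represented.

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely on synthetic fixtures:
3–6-nucleotide structures, training sets of up to 5 positives and 5
negatives, 20 randomized planted scenarios, Shrake–Rupley at 960 points
cross-checked against 2×10⁵-sample Monte-Carlo estimates. These sizes
exercise every code path — multi-structure profiles, jittered positives,
burial, cross-class substitution, clash screening — while keeping the full
suite in the order of a minute.
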