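---
title: "foldsmith: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{foldsmith: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the backbone model, the fold-definition formalism, the folding engine and
its filters, the sequence-design and descriptor layers, the stability
classifier, and the numerical choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` do not themselves compute.

## Backbone model

A chain is represented by its N, CA, C and O atoms plus the backbone
torsions phi/psi/omega (IUPAC convention; degrees in (-180, 180]).
Coordinates are built from torsions by sequential natural-extension
(NeRF-style) internal-coordinate construction using fixed ideal bond
geometry: N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, C=O 1.231 Å; angles
N–CA–C 111.2°, CA–C–N 116.2°, C–N–CA 121.7° (standard stereochemical
library values). The carbonyl O of residue *i* is placed in the C(*i*)
plane trans to N(*i*+1), with a virtual trans next-N for the terminal
residue. phi of residue 1 and psi/omega of the last residue are undefined
and carried as `NA` sentinels; the torsions-to-coordinates-to-torsions
round trip is exact to 1e-6 degrees (a tested invariant). The construction
also runs in reverse (placing residue *i*−1 from residue *i*), which is how
the engine prepends elements to an already-built context without touching
its coordinates.

Omega is a real degree of freedom here, not a fixed 180°: samplers draw it
from a tight trans distribution (SD 3°) and the rama/omega filter rejects
unintended cis peptides.

## The ABEGO alphabet

Torsion space is partitioned into five bins: `O` iff |omega| < 90° (cis);
otherwise for phi < 0, `A` when psi ∈ [−75°, 50°) else `B`; for phi ≥ 0,
`G` when psi ∈ [−100°, 100°) else `E`. These boundary numbers are this
package's commitment (the alphabet is conventionally shown graphically);
they place canonical alpha (−57, −47) in `A` and canonical beta
(−135, 135) in `B`, and the partition property is tested against a
brute-force region oracle on a 1° grid.

Fragment sampling is analytic rather than database-derived: per-letter
truncated Gaussians around canonical centres — A(−63, −42), B(−135, 135),
E(75, 170), G(75, −10); SD 10° for A and 20° for the other letters, omega
trans 180° ± 3° — rejection-sampled so a draw always classifies back to its
letter. A fragment file format (`#abego` header plus torsion rows) lets
users substitute fragments harvested from real structures. Within the
folding engine, helix and strand residues use a tightened SD (scale 0.6)
because idealised elements, not torsion diversity, are what the engine
needs from them; loops sample at the full region width.

## Fold definitions

A fold is declared, in an equivalent YAML or XML dialect (schema
`foldsmith/1`), as an ordered list of segments (helix/strand/loop) with
inclusive length ranges, loop ABEGO menus, sheet declarations (spatial
strand order), pairings (strand-strand with orientation, register range
and optional bulges; helix-helix with orientation; helix-sheet), and
distance constraints between named-segment anchors (N-end, C-end,
midpoint). Defaults are applied at parse time: constraints default to an
8 Å harmonic target with a 2 Å SD — the package-wide default separation
for sheet and helix distances — and bounded constraints add a flat-bottom
half-width of 1 Å (the flat width is an open parameter; 1 Å is this
package's default). Unknown elements are hard errors.

Register semantics: antiparallel register 0 aligns the first residue of
one strand with the last of its partner; a bulge at strand-local index *k*
is itself unpaired and shifts the register of all later residues by one,
which is how sheet curvature is induced. Sheet validity requires, for
every combination of length and register choices (full enumeration up to
20,000 combinations, corner sampling beyond), that interior strands have
no unpaired residues; edge strands may overhang.

The packaged example folds (three-helix bundle, ββαβ, ferredoxin βαββαβ,
beta-grasp) include, beyond the 8 Å defaults, orientation-anchoring
constraints such as "helix C-end to strand C-end, 9–10 Å". These mirror
the per-fold adjustments the formalism exists to express: a βαβ crossover
is only buildable when the helix's C-terminus ends up near the docking
site of the strand that follows it, and a ranged fold definition carries
that knowledge as an ambiguous distance constraint rather than a fixed
residue pair.

## Divide-and-conquer planning

The planner chooses the smallest contiguous window (by minimum residue
count; ties broken by document order) that contains a complete strand or
helix pairing, then repeatedly extends the window by one
secondary-structure element, always choosing an element that pairs with
something already built (helix-sheet pairings anchor a helix to any built
strand of its sheet; elements participating in no pairing attach by
adjacency; a fold with no pairings folds as a single task). When both
directions are possible the smaller extension wins, then document order.
The plan is deterministic, covers every segment exactly once, and for the
canonical ββαβ topology produces hairpin → helix → third strand.

## The Monte-Carlo engine

Each task folds a window whose context residues (if any) are frozen; new
residues start from the extended chain (180, 180, 180). Moves are
3-residue fragment replacements drawn from the per-letter banks, mixed
1:1 with small local tweaks (Gaussian nudges of ±4° on phi/psi, ±1° on
omega) that must keep the residue inside its assigned ABEGO region and
within 12° of trans omega. The tweak moves matter: bank draws alone give
the chain no way to refine an almost-correct geometry, and measured
per-trajectory success rates on a test hairpin rose from a few percent to
roughly 70% when they were added.

The objective is a weighted sum of: clash count (backbone heavy-atom
pairs under 2.5 Å from residues ≥ 2 apart; weight 10; pairs internal to
the frozen context are constant and skipped), harmonic/bounded
distance-constraint penalties in SD units, residue-level pairing
restraints derived from the declared pairings (strand partner CAs at
4.9 Å, SD 0.5; helix-helix and helix-sheet midpoint/end anchors at the
8 Å default, SD 2 — for helix pairs the N/C-end anchors are crossed for
antiparallel orientation, which encodes the orientation in distance
geometry), and a per-residue secondary-structure term that charges
residues whose torsions have not yet been set from their letter's bank.
Temperature anneals geometrically from 10 to 0.3 score units over 3,000
moves; a trajectory aborts early if its best score is still above 25
after 1,200 moves (a hopeless-geometry cutoff), and a task runs up to 8
trajectories before the Perturber permutes one parameter class (lengths →
loop ABEGO → register → torsion reseed, in rotation, never reproducing
the identical tuple), up to 30 permutations. If a task exhausts its
budget the whole build restarts from scratch, up to 3 times: failure is
usually caused by an unluckily placed *earlier* element, which no amount
of perturbation of the current task can repair, so a cheap global restart
dominates deeper local search. These budgets are this package's own
calibration for desk-scale runs (seconds for helix bundles, tens of
seconds to minutes for mixed alpha/beta folds).

A subsegment succeeds only when the extended chain passes every filter
*and* every intended strand-pair partner lies inside the pleated-sheet CA
window (4.2–5.7 Å) — the engine-level realisation of the "no unpaired
residues" rule. Success-status builds therefore re-pass the full filter
battery by construction, which the tests verify.

## Filters

All filters are pure functions of chain + configuration. Secondary-
structure identity maps measured ABEGO letters to H/E/L (A→H, B/E→E) and
requires a perfect match on element interiors, exempting each element's
terminal residue and its neighbour. The helix-kink filter fits local axes
to the first and last 4-residue windows (axis via the second-difference
construction on consecutive CA quadruples, which is exact on ideal
helices) and requires bend < 15° for every helix; helices too short to
evaluate pass with a note. Distance constraints pass within 2 SD
(bounded: plus the flat width). Strand pairing measures the realised
register as the shift maximising partner CAs inside 4.2–5.7 Å, and checks
it and the orientation (sign of the strand direction dot product) against
the intent. Rama/omega allows 5° of drift beyond a region boundary and
20° deviation from trans omega (O-assigned residues exempt). The
tolerances reject genuine outliers without fighting sampler noise.

## Sequence design

Burial is a backbone-only proxy: the number of CA atoms within 8 Å of a
residue's CA and inside a 100° half-angle cone around its CA→pseudo-CB
direction (virtual CB at the ideal tetrahedral position). Core ≥ 5,
surface ≤ 2, boundary between. The radius and thresholds follow the
module contract; the cone half-angle is this package's calibration,
chosen once so that the middle helix of an ideal three-helix bundle is
majority buried — with CA-only counting, narrower cones see almost
nothing. The `plain` protocol draws every position from its layer's
palette (core hydrophobic, surface polar/charged, boundary mixed), with
helix N-caps preferring S/T/N/D and positive-phi loop residues assigned
glycine. The `motif` protocol first seeds core position pairs from a
pair-motif table (residue pair + CB-CB distance window + orientation
class), walking pairs by increasing CB distance and assigning each
position at most once. The packaged ~40-motif table is a toy,
hydrophobic-pair-biased stand-in for a database harvested from crystal
structures; the documented format accepts a real table. There is no
rotamer packing or all-atom scoring: the palettes and motifs capture the
combinatorial layer of the protocol, nothing else.

## Descriptors and stability utilities

Shape descriptors per design: consecutive element centroid distances; the
helix midpoint distance Hm-d; the helix dihedral H-dih through (H1 N-end
axis point, H1 centroid, H2 centroid, H2 C-end axis point), with axis
points obtained by projecting the terminal CA onto the fitted axis line;
opening angles H1a/H2a between each helix axis and the sheet's mean CA
plane (via principal components); the sheet dihedral through the
outer-strands' end CA centroids (180° = flat sheet); and the measured
register of every strand pairing. All are rigid-motion invariant, and
mirroring flips the dihedral signs (tested). Ensemble correlations are
plain Pearson with pairwise-complete NA handling. The combined stability
score of a design is min(trypsin, chymotrypsin) — one protease cleaving
the design means it is unfolded regardless of the other — and a fold's
success rate is the fraction of designs strictly above 0.5, with
cumulative per-bin counts alongside.

## Stability classifier

Features are name-keyed and registry-driven; the default registry has 15
entries, including local-geometry fragment agreement (mean CA RMSD of
9-residue windows rebuilt from the design's torsions against the same
windows rebuilt from ideal secondary-structure torsions; loops compare
against themselves so the measure isolates element quality),
buried-hydrophobic count, contact-network degrees (contacts = CA pairs
< 8 Å, separation ≥ 2), the hub-residue burial proxy (degree × burial of
the most connected residue, ties to the lowest index), net charge, length
and composition fractions. The registry is deliberately a representative
subset — the full feature catalogue of the original study lives outside
its text — and users extend it by appending named functions.

Training wraps the standard random-forest implementation with the study's
configuration: 500 Gini-criterion trees, bootstrap resampling, sqrt(p)
features per split, generalisation estimated from out-of-bag samples and
by fivefold cross-validation. ROC AUC is rank-based with average-rank tie
handling (the normalised Mann–Whitney statistic), tested against an
O(n²) pairwise oracle. Dropout evaluation holds out one fold family at a
time, trains on the rest, scores the held-out fold, and repeats three
times with fresh seeds, reporting min/median/max per fold plus a
whole-set (out-of-bag) AUC and a mixed stratified-holdout AUC; folds with
a single class are flagged and excluded.

The synthetic benchmark generator draws designs from several fold
families with fold-specific shifts confined to two nuisance features,
while the stable/unstable label depends only on fold-independent
features. Its default labels are fully feature-determined (the separable
regime the recovery criteria describe); a logistic-noise mode is
available for realism, and effect = 0 produces pure coin-flip labels.
What passing these tests shows is that the pipeline recovers transferable
signal when it exists and reports chance when it does not; it does not
show that the packaged 15 features suffice for real proteins.

## Problem sizes and known limitations

The test suite and acceptance script run everything at desk scale: the
buildability study uses 50 seeded ferredoxin builds with scaled-down
engine limits (6 trajectories, 12 perturbations, 2 restarts, 2,500 moves
per trajectory), classifier experiments use 240–600 synthetic designs and
150–500 trees, and geometric property suites run on chains of 10–60
residues. Known limitations: no all-atom energetics anywhere (clash +
constraint geometry stands in for a scoring function); no hydrogen-bond
evaluation in strand pairing (a CA distance window stands in for it); the
burial proxy is backbone-only; loop menus are packaged heuristics rather
than mined statistics; and mixed parallel/antiparallel sheets are
expressible but the engine's feasibility degrades as crossover
constraints accumulate, so not every declarable fold is buildable within
default budgets.
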