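---
title: "Element-specific persistent homology for molecular featurization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Element-specific persistent homology for molecular featurization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topomol)
```

## The problem

Machine-learning models of protein–ligand binding and virtual screening
need a fixed-length numerical description of a 3-D molecular structure.
Plain persistent homology of the atomic point cloud is too lossy: it
collapses chemically distinct atoms into indistinguishable points, and for
small molecules its dimension-0 barcode mostly restates covalent bond
lengths.  `topomol` implements the family of element-specific
constructions that repair this — persistence over element/role-selected
atom subsets, over bond-aware and interface-aware filtration matrices, and
over a charge-aware electrostatic axis — together with the vectorizations,
barcode-space metrics, learners and screening metrics that turn those
barcodes into predictions.

## Filtrations

All Vietoris–Rips computations run on a `FiltrationMatrix`: a symmetric
matrix of filtration values with an *excluded-pair* mask.  Excluded pairs
never form edges at any filtration value.  This is the cleanest
representation of the "distance set beyond the filtration cap" device:
no magic large number is chosen, and the construction is exact for any cap.
These matrices deliberately need not satisfy the triangle inequality; the
Rips construction only needs a symmetric entry per pair.

- **Euclidean** (`euclidean_matrix`): pairwise distances in Å.
- **Multi-level** (`multilevel_matrix`, level *n* ≥ 1): pairs within *n*
  covalent-bond hops are excluded.  Hop distance is the BFS shortest path
  on the bond graph.  When a structure has no bond records, bonds are
  perceived geometrically: a bond is declared when the interatomic
  distance is at most 1.3 × the sum of covalent radii.  When a matrix is
  built on an element-selected *subset*, hop distances are still taken on
  the full molecular bond graph — two selected atoms joined through an
  unselected bridging atom are 2 hops apart, not unreachable.
- **Interactive** (`interactive_matrix`): only cross-partition
  (protein–ligand) pairs keep their base values.  The base may be the
  Euclidean or the electrostatic matrix, so the two constructions compose.
- **Correlation** (`correlation_matrix`): `1 − Φ(d; η, ν)` with the
  Lorentz kernel `Φ = 1/(1+(d/η)^ν)` (ν defaults to 2).  The scale η is
  per-pair; its default is the sum of the two atoms' van der Waals radii,
  the natural "contact distance" scale, overridable per call.
- **Electrostatic** (`electrostatic_matrix`):
  `Φ = 1/(1+exp(−c·qᵢqⱼ/d))` with default `c = 100` and *d* in Å,
  unscaled.  With `c > 0` attractive pairs map into (0, 0.5) and enter an
  increasing-Φ filtration early; weak or distant interactions sit near
  0.5.  The filtration axis is [0, 1] and proceeds in increasing Φ, which
  is the orientation implied by the decile bins of the registered
  electrostatic feature groups.

The rigidity index `μᵢ = Σⱼ Φ(d_ij)` and the screened charge-density field
`μ_c(r) = Σⱼ qⱼ exp(−‖r−rⱼ‖/ηⱼ)` are provided as scalar evaluators
(`rigidity_index`, `charge_density`); a cubical-complex filtration of the
density field is out of scope.

## Persistence

`rips_persistence` enumerates simplices up to one dimension above the
requested homology dimension (capped at 2) and runs standard Z2
boundary-matrix column reduction in filtration order, in compiled code.
Ties are broken by (value, dimension, lexicographic vertex order);
barcodes are invariant to the tie-break, which the oracle tests verify.
Zero-persistence pairs are dropped.  Classes alive at the cap are reported
as OPEN bars (death = `Inf`); one OPEN dim-0 bar remains per connected
component of the cap graph.

`alpha_persistence` computes the Delaunay triangulation by exhaustive
circumsphere tests and assigns each simplex the radius at which its
longest edge reaches `2r`, i.e. an edge of length `L` enters at
`r = L/2`.  The implementation is rank-adaptive: collinear inputs reduce
to a sorted chain, planar inputs to circumcircle tests in the best-fit
plane, general inputs to circumsphere tests in 3-D.  Cospherical ties
(e.g. the four corners of a square) are resolved by *including* every
tied simplex: the result is still a valid filtered complex, dim-0
behaviour is unaffected, and no arbitrary perturbation enters the output.
All-coincident input is a domain error.

Two independent oracles guard the engine: `persistence_oracle_0d`
(Kruskal/union-find single linkage) and `persistence_oracle_reduction`
(plain-R column reduction over an explicit simplex list).  The test suite
enforces bar-multiset equality on hundreds of random inputs.

Default caps follow the bin ranges of the registered recipes: 12 Å for
complex-scale features, 5 Å for ligand alpha features, 1.0 for the
electrostatic axis.  OPEN bars are retained in barcodes; each vectorizer
decides their treatment (below).

## Vectorization

**Counts in bins** (`counts_in_bins`) returns three vectors per dimension:
births per bin, deaths per bin, and bars whose interval overlaps the bin
(`birth ≤ r_i` and `death ≥ l_i`).  The overlap form is the informative
reading of the persistence count — the disjunctive form would count nearly
every bar in every bin.  An OPEN bar falls in no death bin but overlaps
every bin right of its birth.  In the registered feature groups, dimension
0 contributes death counts only (births are identically zero and every
live bar overlaps every bin); the 2-D image keeps both the dim-0 death and
overlap channels, where the per-bin overlap profile is informative as an
image row.

**Barcode statistics** (`barcode_statistics`): mean, population standard
deviation (n divisor; a singleton has SD 0), max, min, sum, count for the
Birth and Death sets, and the same six plus the longest bar's birth and
death for the Persistence set (8).  Dimension 0 contributes the Death
block only.  OPEN deaths are capped at the barcode cap first; empty sets
give all-zero blocks with count 0.

**Slice statistics** (`slice_statistics`): bars are partitioned along one
axis into bins and each slice is summarized by the statistics of the
complementary coordinate(s): death-sliced → Birth stats, birth-sliced →
Death stats, persistence-sliced → Birth and Death stats.

**2-D image** (`build_2d_image`, `complex_2d_image`): per element
combination, the eight channels F_d(B⁰), F_p(B⁰), F_b(B¹), F_d(B¹),
F_p(B¹), F_b(B²), F_d(B²), F_p(B²); for complexes, eight further channels
hold complex-minus-protein count differences (16 total).  The default
configuration is 120 bins on [0, 12] Å × 128 combinations × 16 channels.
The combination axis is "ordered by importance": importance orders are
learned on a task (e.g. from per-combination model scores) and passed in;
the package stores and reuses whatever order it is given, defaulting to
the registered list order.

**Feature groups** (`assemble_features`): registered recipes fix the
complex type, scheme, dimensions, combination list, vectorizer, bins and
parameters, making the schema a pure function of the config.  The
single-molecule combination lists deserve a note: the 32-entry list is 16
heavy-atom combinations plus the same 16 with H appended, and the
36-entry list adds CCl/CClH/CBr/CBrH; a bare "H" selection is not
included, which is what makes the 32/36 counts internally consistent.

## Barcode metrics

`wasserstein_distance` (default p = 2) solves the optimal partial
matching exactly: the cost matrix is augmented with one diagonal slot per
bar (cost λ^p, λ = half-persistence), diagonal-to-diagonal slots cost 0,
and a Hungarian assignment gives the minimum penalty.
`bottleneck_distance` binary-searches the candidate penalty values with a
bipartite-matching feasibility test.  Both are exact — inputs are small —
and both are verified against an exhaustive enumeration of all partial
bijections for barcodes up to 4 bars per side.  OPEN bars are capped at
the barcode cap before any metric computation, which is required for λ to
be finite.  λ enters the p-power sum as λ^p with no extra factors.

`molecule_similarity` averages d₂ over six barcode sets — dimensions
0/1/2 under the Euclidean and level-1 multi-level matrices — for five
ligand element combinations (CNOS, CNOSPFClBrI, NOH, CNO, CNOSPFClBrIH),
as a flat mean over all (scheme × combination × dimension) entries; the
entry list is configurable.

## Learners

KNN regression (`knn_predict`, default k = 3) takes a precomputed
distance matrix and averages the k nearest training targets, with ties
broken by stable training order and a leave-one-out mode.

Tree ensembles go through installed backends behind one surface
(`fit_predict_trees`): gradient boosting via xgboost, random forest and
extremely randomized trees via ranger.  Registered defaults: regression
GBT 20000 estimators, depth 8, learning rate 0.005, subsample 0.7,
square-root feature fraction; screening GBT 2000 estimators, subsample
0.5, learning rate 0.01, positive:negative class weight 100:1 (mapped to
xgboost `scale_pos_weight = 100`); RF/ET 2000 trees with balanced class
weights (ranger per-class case weights inversely proportional to class
frequency — ranger has no per-bootstrap rebalancing, and this is the
closest single-shot equivalent).  All fits are single-threaded with a
fixed seed, so identical inputs give identical predictions.  Tests and
the synthetic screening experiment use 500 estimators; the registered
defaults are unchanged.  `vote_classifiers` averages voter probabilities
and `consensus_average` averages prediction vectors, including externally
produced ones.

## Screening evaluation

`auc` implements the ranking form directly: one minus the mean, over
actives, of the fraction of decoys ranked above each active; decoys tied
with an active count one half (the Mann–Whitney convention — the formula
is silent on ties).  `enrichment_factor` uses `N^x = ceiling(xN/100)` top
compounds (rounding convention chosen once; at screening-library sizes
the difference from floor is negligible, on toy sets ceiling keeps
EF₁₀₀ = 1 exact).  `leave_one_target_out` trains the voting ensemble on
all other targets, minus a configurable per-target exclusion map, and
reports per-target AUC/EF₂/EF₂₀ plus unweighted averages.

## Synthetic data

The generators are pure functions of their arguments (the RNG state is
seeded and restored around each call), so every fixture is reproducible
byte-for-byte.

- `make_point_cloud`: canonical shapes (line, square, circle, regular
  tetrahedron) with oracle-known barcodes, plus uniform random clouds.
- `make_toy_molecule`: a connected bonded tree grown atom by atom with
  bond lengths uniform in 1.3–1.8 Å and a 1.5 Å clash floor — the bond-
  length range of organic single/double bonds; charges uniform in
  [−0.5, 0.5], centred to sum to zero, mimicking a Gasteiger-like
  assignment.
- `perturb_conformation`: a *conformational* change, not noise — random
  torsions about bridge bonds, rescaled until no atom moves more than the
  requested magnitude.  Bond lengths are preserved exactly, which is what
  makes the demonstration sharp: the Euclidean dim-0 barcode (essentially
  the bond-length multiset) cannot distinguish the conformers, while the
  level-1 dim-1/2 barcodes can.
- `make_screen_set`: per target, a rigid icosahedral cage of 12
  protein-role atoms (radius 6 Å) — the simplest geometry with nontrivial
  dims 1–2 — with fixed random elements and charges.  Each compound is a
  toy ligand centred in the pocket with 4 contact atoms placed along
  pocket-vertex directions.  Actives receive contacts at 2.8–3.5 Å
  (hydrogen-bond to van-der-Waals contact range) with opposite-sign
  contact charges of magnitude 0.4·min(effect, 1); decoy contact
  distances are inflated by effect × U(0.5, 2) Å and their contact
  charges carry random signs.  At effect 0 the two classes are drawn from
  identical distributions, so any classifier's expected AUC is 0.5 by
  construction.

What the fixtures do *not* emulate: forcefield-realistic geometry, bond
angles and torsional preferences, protein secondary structure, docking
pose errors, or the property-matched decoy selection of real screening
benchmarks.  Tests passing on these fixtures demonstrate that the
machinery — selection, filtration, persistence, vectorization, learning,
evaluation — is correct and that planted geometric/electrostatic signal
is recoverable end-to-end; they do not certify performance on real
protein–ligand data.

## Numerical choices and degenerate inputs

- Excluded pairs are omitted from complex construction entirely rather
  than assigned a large sentinel.
- Delaunay tolerance 1e-9 (relative); cocircular/cospherical ties all
  included (see above).  For the four corners of a square this keeps both
  diagonal triangles — harmless for persistence, and deterministic.
- Empty element selections produce empty barcodes and all-zero feature
  blocks, keeping schemas fixed.
- A selection with a single atom yields one OPEN dim-0 bar, capped by the
  vectorizers at the group cap.
- Ligand Rips statistics groups cap at 12 Å (covers toy-ligand
  diameters); ligand alpha groups at 5 Å, matching their bin range.
- Monte-Carlo/experiment sizes used by the tests and the acceptance
  script: 1000 AUC replicates (200 actives / 2000 decoys); screening
  experiments with 2 targets × (20 actives + 60 decoys) and 500 trees per
  voter; oracle sweeps over 50 clouds (n ≤ 7), 100 matrices (n ≤ 15),
  500 barcode pairs and 200 triples.  These sizes give stable results
  (the random-AUC estimate has a standard error near 0.002) while keeping
  the whole suite fast.

## Known limitations

- Homology dimensions above 2, zigzag and multiparameter persistence are
  out of scope.
- The alternative charge correlation `q_i q_j exp(−d/η)` (a signed,
  unbounded axis) is not implemented.
- The brute-force Delaunay construction is exact but O(n⁵); it is meant
  for binding-site-scale point sets (≲ 100 atoms), not whole proteins.
- Deep convolutional models are not included; `consensus_average` accepts
  externally produced prediction vectors so such models can join a
  consensus.
- The Mol2 reader covers the ATOM/BOND blocks with charges — the subset
  the featurization needs — not the full SYBYL specification.

```{r example}
lig <- make_toy_molecule(10, seed = 1)
b <- rips_persistence(
  multilevel_matrix(lig, build_bond_graph(lig), level = 1),
  max_dim = 2, cap = 12)
b
bars_of_dim(b, 1)
```
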