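---
title: "Topological analysis of folding trajectories: methods and design"
author: "phfold authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological analysis of folding trajectories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phfold)
```

## The problem

Molecular-dynamics ensembles of a folding protein contain far more
geometry than a human can read. phfold condenses each snapshot of a
C-alpha trace into its *loop content* — which groups of residues enclose
empty space, and how robustly — and then asks how that loop content evolves
as the chain folds. The pipeline has six stages:

1. **Preprocessing.** Frozen-coordinate snapshots (all atoms at one
   identical point, an artifact of merging distributed-computing output)
   are removed, and only trajectories whose minimum Kabsch RMSD to the
   native structure is strictly below 1.0 Å are kept. The strict
   inequality is deliberate: a tie at the cutoff is excluded.
2. **Persistent homology.** For each snapshot, the alpha-complex
   filtration of the C-alpha point cloud is built on its Delaunay complex,
   and degree-1 persistence pairs (b, d) are computed by Z2 boundary-matrix
   reduction. Degree 1 (loops) is the only degree computed: helix turns and
   inter-helix pairings are loops, while component counts and cavities
   carry little information about tertiary-structure formation at this
   resolution.
3. **Volume-optimal cycles.** Each pair is localized by the smallest set
   of triangles whose Z2 boundary consists of edges alive at the birth
   radius; that boundary is the representative loop reported for the pair.
4. **Vectorization.** The "bag of simplices": every unordered residue pair
   (i, j) receives the summed lifetimes d - b of the volume-optimal cycles
   whose edge set contains (i, j), giving an R(R-1)/2-dimensional
   non-negative vector per snapshot (595 dimensions for 35 residues).
5. **Dimension reduction.** Non-negative matrix factorization of the
   stacked feature matrix V ≈ WH (Frobenius objective, multiplicative
   updates), with basis columns rescaled to unit norm so the coefficient
   scores are in Å. Candidate ranks are judged by the residual-sum-of-
   squares curve and by the cophenetic correlation of consensus
   clusterings over repeated runs.
6. **Flow fields.** The per-snapshot scores form trajectories in reduced
   space; finite-difference velocities binned on a regular grid give a
   mean-velocity flow field, density histograms, velocity-distribution
   histograms inside a region, and a two-path classification of folding
   routes by the order in which two score components first cross a
   threshold.

## Units and the radius convention

Filtration values are ball **radii** in Å, not squared radii. Some alpha
complex implementations natively report squared radii; here every value
that leaves the homology module is a radius, so lifetimes, bag-of-simplices
weights, and (because basis columns are unit-norm) NMF scores are all in Å.
All downstream thresholds quoted in Å assume this convention.

## The synthetic trajectory generator

The package ships a generator rather than depending on an external MD data
set. It emulates a 35-residue, three-helix bead chain (one bead per
residue; helices at residues 3–10, 14–19, 22–32 with 1.5 Å rise, 2.3 Å
radius, 100°/residue twist) whose native state is a compact antiparallel
bundle. Two planted contact sets of two residue pairs each bridge helices
1–3 (mimicking a terminal-subdomain pairing such as 9–32 with 6–29) and
helices 1–2 (8–15 with 5–18). A folding trajectory starts from an extended
coil (3.8 Å spacing, seeded jitter), moves along a deterministic monotone
progress coordinate through an intermediate in which only the plan's first
contact set is docked, reaches the native state at 80% progress, and sits
at the native state thereafter; i.i.d. Gaussian noise (default
sigma = 0.25 Å per coordinate) is added per frame. Plan A docks helices
1–3 first; plan B docks 1–2 first; the two plans differ only in this
order. Non-folding trajectories are persistent-random-walk coils kept at
least 3 Å RMSD from native by rejection. Frozen tails replicate the
all-atoms-at-(22.5, 22.5, 22.5) artifact.

Design choices worth stating explicitly:

* **Intermediates.** With helices 1 and 3 docked, the middle block (helix
  2 plus linkers) is rebuilt as an outward Bézier detour anchored at its
  two flanking residues, which preserves chain continuity and creates a
  large, long-lived loop through the 1–3 contact — the topological
  signature of that docking. With helices 1 and 2 docked, the C-terminal
  block extends as a straight arm. A hinge rotation was rejected because
  the hinge axis passes too close to helix 2 to break its contacts.
* **No physics.** There is no force field, excluded volume, or
  thermodynamics; the analysis consumes geometry only, and the generator's
  job is to produce controlled geometry with a known ground truth.
  Consequences: synthetic ensembles are far more homogeneous than real MD
  (identical progress schedules up to noise), the unfolded basin is
  underexplored, and the absolute scale of lifetimes is not comparable to
  real proteins. Passing tests demonstrate the correctness of the
  machinery and the recoverability of planted structure, not biological
  conclusions.
* **Determinism.** Every generator is a pure function of its parameters
  and one integer seed; no global RNG state is consumed or disturbed.

## Numerical choices in the homology core

* **Delaunay by brute force.** Snapshots have a few dozen points, so the
  Delaunay complex is computed by exact empty-circumsphere enumeration
  over all 4-subsets (in C++), rather than an incremental triangulation.
  Tetrahedra whose determinant is below a relative flatness threshold
  (1e-12 on the edge-length scale) are skipped.
* **General position.** A deterministic seeded jitter of 1e-9 Å is applied
  before triangulation; the emptiness test is a pure strict inequality, so
  the jitter (not a tolerance) breaks cospherical ties. The jitter seed is
  recorded in every output.
* **Planar and 3-point clouds.** Near-planar inputs (thickness below 1e-6
  of the spread, or fewer than 4 points) are triangulated in their
  principal plane with a 2D alpha complex; only (numerically) collinear
  input is rejected. This keeps planar fixtures — triangles, pentagons —
  first-class citizens.
* **Alpha values.** A simplex that is Gabriel (its minimal circumscribing
  ball is empty) enters at its circumradius; otherwise it inherits the
  smallest coface value. A final monotonicity pass clamps any face value
  to its cofaces' minimum, so the face-ordering invariant holds exactly.
* **Zero-persistence pairs** (death equal to birth within 1e-10 relative)
  are dropped; they are an artifact of non-Gabriel simplices entering with
  their cofaces.
* **Volume-optimal cycles** are found by exact iterative branch-and-bound
  over Z2 triangle sets: always fix the first uncovered forbidden boundary
  edge, branch over the admissible triangles containing it (banning
  skipped alternatives to avoid duplicate states), prune with
  size + ceil(uncovered/3) against the incumbent, and warm-start with the
  feasible volume read off the persistence reduction (the accumulated
  triangle combination whose reduced boundary is the birth cycle). Ties in
  volume size are broken by the lexicographically smallest sorted edge
  list, which the tie enumeration makes deterministic. A node budget
  guards against pathological inputs; exceeding it raises an error rather
  than returning a suboptimal cycle.

## NMF choices

* Multiplicative updates with an epsilon of 1e-12 in denominators;
  objective recorded every iteration and non-increasing; stopping at
  relative objective change below 1e-6 or 2000 iterations (defaults chosen
  as conventional values; the fits used here converge in a few hundred).
* Unit-norm basis columns resolve the diagonal scaling ambiguity; the
  residual permutation ambiguity is resolved by sorting components by
  descending coefficient mass.
* **RSS inflection.** The discrete second difference of the RSS curve is
  computed at interior ranks. A rank is selected only when its positive
  curvature dominates (more than half of the total positive curvature);
  otherwise the report states that no inflection exists. A plain
  sign-change rule is too brittle: after the true rank the second
  difference fluctuates around zero, and its first sign change lands one
  rank late on clean data while firing spuriously on noise. Heterogeneous
  ensembles genuinely yield near-linear RSS curves, and "no inflection" is
  then the honest answer.
* **Cophenetic criterion.** For each rank, repeated seeded fits assign
  each sample to its argmax component (ties to the lowest index); the
  consensus matrix over runs is converted to a dissimilarity, and the
  cophenetic correlation of its average-linkage dendrogram measures
  stability; the selected rank maximizes it, smallest rank on ties. A
  constant dissimilarity (perfectly stable one-block clustering) is
  defined to have coefficient 1. The number of runs (30) and the linkage
  (average) are conventional defaults; the method's discriminative power
  comes from sub-rank factorizations being initialization-dependent, so
  validation data must have symmetric (equidistant) clusters — the
  `simulate_block_factors()` generator — or the sub-rank merge is
  data-determined and spuriously stable.

## Flow-field and path-classification choices

* **Velocity** is the per-frame score displacement (Å per frame interval),
  attributed to the earlier frame's position, never spanning trajectory
  boundaries. No time normalization is applied.
* Cells with **count <= min_count** (default 100, "more than 100" read
  strictly) report counts but no velocity.
* Grid ranges come from the data minimum/maximum per axis and are stored
  with the field for reproducibility.
* **Path classification** is this package's operationalization of the
  two-route picture, not a statistic the persistence analysis defines: a
  trajectory is A when the first selected component crosses its threshold
  strictly before the second, B otherwise, "unresolved" when neither
  crosses. The components are selected per contact set as the coefficient
  rows best correlated with the feature mass on the whole inter-helix
  bridge (helices extended by two flanking residues, shared edges
  removed). Correlating against the full bridge rather than the planted
  pairs alone matters: the volume-optimal cycles of partially docked
  conformations run through bridge edges adjacent to, but not identical
  with, the planted pairs. Thresholds are data-driven — half the median
  late-stage score of the trajectories expressing the component — so they
  scale with the fitted basis rather than being absolute Å values. Before
  crossing detection the score series are smoothed with a trailing
  three-frame moving average (`smooth_scores()`): an isolated one-frame
  score blip is not a formation event, and without smoothing such blips
  can register as spurious early crossings.

## Problem sizes used in validation

The shipped tests and the acceptance script exercise: 8-point clouds
against a naive full-boundary-matrix reduction oracle (50 clouds);
volume-optimal cycles against exhaustive subset search on complexes with
at most 20 triangles; NMF recovery at N = 595, M = 2000, rank 5 with 5%
multiplicative noise over 5 seeds; cophenetic rank selection at
N = 60, M = 150, planted rank 5, ranks 3–8 with 30 runs per rank; a
preprocessing ensemble of 20 folding, 10 non-folding and 5 frozen-tail
trajectories; and an end-to-end two-path run of 100 folding trajectories
(50 per plan) at 30 frames each. These sizes were chosen so the full
validation is a desk-scale computation while every stage still operates in
its intended regime.

## Known limitations

* The brute-force Delaunay step is O(n^5); it is comfortable for chains up
  to ~60 residues and unsuitable for all-atom clouds.
* The volume-optimal formulation here constrains triangle values and
  boundary edges; it does not impose connectedness of the volume, which
  stricter formulations add. On the complexes tested the optima coincide
  with exhaustive search, but adversarial inputs could differ.
* The generator's two-path structure is planted and clean; real ensembles
  mix paths, revisit states, and contain many more conformational modes
  than the synthetic rank-5 structure.
* `classify_paths` assumes exactly two competing routes expressed through
  two score components; more intricate route structures need a different
  readout.

## A short worked example

```{r example, eval = FALSE}
library(phfold)
cfg <- run_config(n_folding = 10, n_nonfolding = 4, n_frozen = 1,
                  n_frames = 20, rank = 4, seed = 1, min_count = 10)
manifest <- run_pipeline(cfg)
print(manifest)
manifest$path_labels
```

The manifest records per-stage counts (which are asserted to be consistent
— snapshots entering homology equal feature-matrix columns), the filter
report, the fitted factorization, the flow field, and the per-trajectory
path labels with their crossing frames.
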