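---
title: "MorphoRates: models, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MorphoRates: models, conventions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MorphoRates)
```

MorphoRates estimates *where on a dated phylogeny* and *when in time*
organismal shape evolved fastest. This vignette records the statistical
model behind each stage, the conventions adopted where the underlying
methods admit more than one reading, the meaning and defaults of every
tuning parameter, and the numerical choices that make results exactly
reproducible.

## 1. The data model

An analysis combines three inputs:

* **Specimens** (`readTPS`): 2-D landmark and/or outline-curve
  coordinates per specimen, one TPS block per specimen, with `ID=`,
  optional `IMAGE=`, `SCALE=`, and `CURVES=`/`POINTS=` records. Each
  character (e.g. mandible, pronotum) lives in its own TPS file. Errors
  are reported with file and line numbers; duplicate specimen IDs and
  inconsistent landmark counts across blocks are rejected.
* **Tree** (`readTimeTree`): one rooted tree, Newick or simple
  (untranslated) Nexus. Node ages in Ma come either from bracketed
  annotations — `[&age=93]`, optionally `[&age_95={66,122}]` — or, when
  no annotation is present, from branch lengths on an ultrametric tree
  (age = depth above the tips). Mixing is resolved conservatively: if
  *any* internal node is annotated, *all* internal nodes must be;
  unannotated tips are taken as extant (age 0). A non-ultrametric tree
  without explicit ages is an error, because its node ages would be
  ambiguous. Unlabeled internal nodes receive deterministic preorder
  labels `Node1` (root), `Node2`, …, so all output tables are joinable
  across runs and characters.
* **Groups** (`readGroupTable`): CSV with `specimen_id`,
  `terminal_group` (the tree tip the specimen belongs to), and
  `feeding_type` (a discrete ecological state drawn from a fixed
  vocabulary; the default vocabulary is omnivory / coprophagy /
  phytophagy / other). `checkGroupsAgainstTree` reports tips and groups
  present on only one side.

## 2. Shape preparation

**Semi-landmarks.** Outline curves are resampled to a fixed number of
points at equal arc-length spacing (`resamplePolyline`), endpoints
pinned to the digitized endpoints. The resampled points are then treated
as ordinary fixed landmarks — there is *no* sliding step. The
four-character demonstration design uses 50 / 25 / 50 semi-landmarks for
mandible / pronotum / elytron outlines and 16 fixed landmarks for the
hindwing (`fourCharacterConfig`).

**Superimposition.** `gpaAlign` performs full generalized Procrustes
analysis: each configuration is centered and scaled to unit centroid
size, then iteratively rotated (no reflection — specimens are assumed
digitized in one consistent orientation) to a consensus that is
re-estimated each round until it moves by less than `tol` (default
`1e-10` in Frobenius norm) or `maxIterations` (100) is reached. Rotation
uses the SVD solution with a determinant guard against reflections.
Aligned coordinates are orthogonally projected onto the tangent space at
the consensus; all downstream statistics operate on these tangent
coordinates. Tangent-space linearity is an approximation valid for
*concentrated* shape samples; the simulation defaults are chosen to stay
in that regime (section 6).

## 3. Ordination and classification

**PCA** (`shapePCA`) is the SVD of centered tangent coordinates;
eigenvalues are `d²/(n−1)`. Axes with eigenvalues below `tol`
(default `1e-10`) relative to the first are dropped — Procrustes data
are rank-deficient by construction (at most `2k − 4` dimensions). Axis
signs follow a deterministic convention (largest-magnitude loading
positive), so scores are bit-reproducible across runs.

**CVA** (`shapeCVA`). Because the pooled within-group covariance `W` is
singular in the raw tangent space, the data are first projected onto
leading principal components. With `priorReduction = "auto"` the
subspace keeps `min(n − g, rank)` components, further capped at 99%
cumulative variance (`varianceFraction`); an integer `priorReduction`
overrides this. In the reduced space the package computes `W` (divisor
`n − g`), pairwise Mahalanobis distances between group means
`sqrt(dᵀW⁻¹d)`, and canonical axes from `eigen(W⁻¹B)` scaled to unit
within-group variance. Euclidean distances between group means are
reported in the full tangent space.

**Confusion matrices** (`classifyConfusion`). Specimens are assigned to
the group with the nearest mean in Mahalanobis distance. *Both*
conventions are provided: resubstitution (reuse fitted means and `W`)
and leave-one-out (refit means and `W` with the specimen held out). The
PCA reduction basis is kept fixed across leave-one-out folds —
re-deriving the subspace per fold would make folds live in different
spaces. Leave-one-out is the default and the honest generalization
estimate; resubstitution is reported alongside because it is the common
legacy convention.

## 4. Ancestral states

**Shapes.** `reconstructShapes` minimizes the sum of squared coordinate
changes along edges, each edge weighted by the inverse of its duration
(`weighting = "branch_length"`; `"equal"` gives unweighted squared-change
parsimony). The minimizer is found *exactly* by solving the weighted
graph-Laplacian linear system — no iteration, no starting-value
dependence. Weighted squared-change parsimony is identical to the
maximum-likelihood point estimate under Brownian motion, which the test
suite verifies against `ape::ace`. Zero-length edges receive weight
`1/ε` with `ε = 1e-8` Ma.

**Discrete states.** `fitchSankoff` implements Sankoff parsimony with an
up-pass/down-pass that reports, per node, the full set of states lying
on at least one most-parsimonious reconstruction (uniform costs reduce
to Fitch). `mkMLStates` implements the equal-rates k-state Markov model
with the closed-form transition probability
`p_ii(t) = 1/k + (1 − 1/k)·e^{−kqt}`, likelihood pruning with
per-node scaling, marginal reconstructions from combined up/down passes
under a uniform root prior, and rate estimation by bounded 1-D
optimization on the log scale.

## 5. Deformation ratios and sequential growth rates

**DR.** For every edge, `edgeDeformations` computes the morphological
distance between the parent and child reconstructed shapes divided by
the elapsed time `Δt` — the *deformation ratio*, a rate in shape units
per Ma. Conventions:

* `Δt` is taken between **mean** node ages. When 95% age intervals are
  present they are carried through as `dt_lo`/`dt_hi` for reporting, but
  never used in the point estimate.
* Two distances are always computed. *Euclidean* is the norm in tangent
  coordinates. *Mahalanobis* requires a metric: the package projects
  ancestral shapes into the CVA space fitted to the **terminal**
  specimens (same centering, PCA projection, and pooled `W`), because
  within-group covariance is only observable at the tips. This is the
  adopted resolution of an under-determined convention; the Euclidean
  column is always available as the assumption-free alternative.
* Non-positive `Δt` is an error by default;
  `zeroLengthEdges = "epsilon"` substitutes `1e-8` Ma with a warning.

**SGR.** Along every root-to-tip path, `sgrAlongPaths` computes the
relative change between consecutive DRs, `(DRᵢ₊₁ − DRᵢ)/DRᵢ` — a
dimensionless acceleration index, invariant to rescaling time or
distance units (verified by the acceptance tests). Each SGR step is
anchored at the midpoint age of its later edge. Steps whose edge is
shared by several paths are flagged (`shared`) so summaries can
de-duplicate; a zero previous DR yields `NA` with a warning, never
`Inf`. `stepChartSeries` lays DR out per lineage over `[parent age,
child age]` intervals — the table behind step-style rate-through-time
charts. `fitTrend` fits ordinary-least-squares polynomials (default
degree 2, capped at the number of distinct ages minus one) or loess
(default `span = 0.75`) on a 100-point age grid.

**Window spreads.** `sgrWindowSummary` de-duplicates shared edges, bins
SGR values by the midpoint age into user windows, and reports per window
and character the count, maximum, minimum, and **spread = max − min** —
the adopted summary of how heterogeneous lineage accelerations were in a
time slice. Empty windows warn and report `NA`.

## 6. The simulator: realism and limits

`simulateBMShapes` evolves a character's mean shape by Brownian motion:
the root is a regular k-gon at unit centroid size, and each child equals
its parent plus i.i.d. Gaussian displacements of variance
`baseRate × multiplier × Δt` per coordinate. Rate shifts are specified
per branch (`shifts = c(t4 = 10)` multiplies the variance on the branch
leading to `t4` by 10). Specimens are the tip mean plus digitization
noise (`noiseSd`, default 0.005), optionally pushed through a random
similarity transform (`jitter`) which GPA must undo. Discrete states
evolve by an equal-rates Markov chain (`simulateDiscreteTrait`).
`makeFixture` writes everything as TPS/Newick/CSV plus a `truth.json`
with the true node shapes, per-edge displacements, and node states.

Defaults (`nTips = 8`, `rootAge = 150` Ma, `baseRate = 1e-4`,
`noiseSd = 0.005`, 10 specimens/tip) keep runtimes in seconds. For
*recovery* experiments the acceptance layer uses `baseRate = 1e-6`:
displacements then stay at a few percent of centroid size, the regime
where tangent-space statistics — and hence truth recovery — are
meaningful. What the simulator deliberately does **not** model:
landmark-level covariance (displacements are isotropic), allometry,
measurement error correlated along outlines, fossil (non-extant) tips,
and any size evolution (GPA removes size anyway). It is a validation
harness, not an attempt at biological realism.

Determinism: every stochastic function takes a seed and runs in a
private RNG stream (`.Random.seed` is saved and restored), so fixtures
are byte-identical across runs and independent of caller RNG state.

## 7. The pipeline and reproducibility

`runPipeline(pipelineConfig(...))` chains all stages per character and
writes: aligned coordinates, PCA scores, Mahalanobis distance matrices,
confusion matrices, per-edge DR tables, SGR tables, step-chart series,
trend fits, ancestral feeding types, window summaries, a per-character
JSON summary, a `run.log`, and a `manifest.csv` of MD5 checksums —
identical inputs give identical checksums. If all specimens share one
feeding type, the feeding-type CVA/classification stage is skipped with
a log note (CVA is undefined for a single group); the terminal-group CVA
still supplies the Mahalanobis distance space. Specimens missing from
the group table abort the run with a full cross-consistency report.

`scripts/acceptance.R --seed <int> --out <path>` runs the
four-character design end to end and adds rate-shift recovery
statistics over 100 seeded replicates (16 tips, 50 landmarks,
×10 shift on one terminal branch, noise-free): with seed 1 the shifted
branch attains the maximal DR in all replicates and the correlation
between true per-edge displacement and estimated Euclidean distance is
0.80 over 3,000 edges. Problem sizes throughout the validation suite
are desk-scale: trees of 2–16 tips (all 1,068 rooted binary topologies
up to 6 tips for the parsimony oracle), 4–50 landmarks, and up to a few
hundred specimens, each suite finishing in well under the times quoted
in `tests/testthat/`.

## 8. Summary of adopted conventions

| Question | Adopted convention |
|---|---|
| Mahalanobis metric for ancestral nodes | project ancestors into the terminal-specimen CVA space (fixed center, PCA basis, pooled `W`) |
| `Δt` under age uncertainty | mean node ages; CI bounds carried as `dt_lo`/`dt_hi`, reporting only |
| Classification convention | both resubstitution and leave-one-out computed; leave-one-out is the default |
| Window summary statistic | spread = max − min of de-duplicated SGR values in the window |
| Semi-landmarks | equal arc-length resampling, then fixed (no sliding) |
| CVA dimensionality | PCA pre-reduction to `min(n − g, rank)` components, capped at 99% variance |
| Zero-length branches | error by default; opt-in `ε = 1e-8` Ma |
| Node naming | deterministic preorder `NodeK` labels, root = `Node1` |
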