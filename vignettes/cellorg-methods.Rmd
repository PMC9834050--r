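---
title: "Shape spaces, PILRs and organization statistics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape spaces, PILRs and organization statistics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cellorg)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, what the synthetic
data generator does and does not emulate, and the design decisions that
were genuinely open. It states no empirical result that the test suite does
not itself compute.

## The shape coordinate system

### Alignment

Cells grown in epithelial-like colonies have a biologically meaningful
apical–basal (z) axis, so alignment only ever rotates in the xy plane,
about the cell centroid, by an angle θ_cell. Two modes exist:

- `longest_axis` (default): the leading eigenvector of the xy
  second-moment matrix of the cell mask is rotated onto x.
- `edge_axis`: a supplied outward direction (e.g. toward a colony edge) is
  rotated onto +x, so that polarization toward the colony boundary reads as
  +x polarization.

The longest axis is only defined up to 180°. *Design choice*: the ambiguity
is resolved by requiring the third central moment (skewness) of the rotated
x coordinates to be non-negative; an exactly symmetric cell keeps the
identity. This convention is deterministic and rotation-covariant, which is
what the downstream invariance tests need; it is a repository decision, not
something the source methodology specifies.

### Spherical harmonic expansion (SHE)

Each aligned surface is written as a radius function r(θ, φ) about its own
centroid and expanded in real, orthonormal spherical harmonics up to degree
L_max = 16, i.e. 289 coefficients per surface and 578 for the joint
cell + nucleus descriptor. The radial parameterization assumes
star-convexity; masks violating it on more than 1% of sampled rays are
**flagged, not rejected**, since the fit degrades gracefully.

Numerical choices:

- The radius function is sampled by ray marching with the binary occupancy
  trilinearly interpolated along each ray and the boundary placed at the
  0.5 crossing. This subvoxel estimator removes the half-voxel negative
  bias a nearest-voxel estimator has (a 12-voxel cell would otherwise lose
  several percent of its radius), which is what lets a radius-8 sphere
  round-trip within 1%.
- Fitting is dense least squares on an equiangular 2(L_max+1) × 4(L_max+1)
  grid (~8× oversampled); the QR factorization of the design matrix is
  cached per L_max, making repeated fits cheap.
- The nuclear expansion is computed about the nuclear centroid and the
  nuclear-centroid offset relative to the cell centroid is carried as
  metadata (`centroid_offset`), so reconstruction places the nucleus
  correctly inside the cell. The offset deliberately does **not** enter the
  PCA descriptor: whether it belonged in the 578-vector was an open
  question, and keeping the descriptor a pure pair of surface expansions
  keeps the shape space interpretation clean.
- Voxelization of a coefficient set uses a bilinearly interpolated radius
  lookup table (65 × 129 in θ × φ) rather than evaluating 289 harmonics per
  voxel; the table error is far below voxel resolution for L_max ≤ 16.

### PCA shape space

PCA of the n × 578 descriptor matrix, keeping 8 modes, each z-scored by
its standard deviation σ so coordinates are in σ units. Conventions:

- **Sign**: each mode is oriented to correlate positively with a declared
  covariate (e.g. cell volume) when one is given, otherwise so its score
  skewness is non-negative. Either way signs are deterministic.
- **Percentile exclusion**: the PCA itself is fitted on all cells; cells in
  the 0–1st or 99–100th percentile of any raw PC are only *flagged* and
  excluded from downstream statistics. Second populations projected into a
  baseline space are never percentile-excluded, because their shapes may
  legitimately live in the baseline's tails.
- **Map point bins**: 9 centers per mode at −2σ … 2σ in 0.5σ steps, with
  nearest-center assignment inside a ±0.25σ half-width (contiguous coverage
  of [−2.25σ, 2.25σ]). The half-width was an open reading ("regular
  intervals"); contiguous nearest-center bins are the simplest consistent
  one. 8 modes × 9 bins with the shared center bin give 65 map points.
- The **8-dimensional sphere** (default radius 2.1σ) selects the
  similarly-shaped reference population by Euclidean norm.

## The intracellular location coordinate system (PILR)

The shell family of a cell interpolates linearly in SHE coefficient space
(offsets included) from a one-voxel-radius sphere at the nuclear centroid
to the nuclear surface (32 shells) and on to the cell surface (64 further
shells). Structure presence (or intensity) sampled at each shell mesh point
forms the PILR matrix, 96 × 2048 at the default 32 × 64 angular grid.

*Discretization*: the source framework implies a fixed PILR size
(532,610 pixels) without stating shell counts or grid; the defaults here
(96 shells, 32 × 64 grid ≈ 197k entries) were chosen once for desk-scale
speed and are documented as *not* matching that internal discretization.
All statistics are correlations over matched discretizations, so this
choice affects resolution, not semantics.

*Morphing* is an inverse mapping: each voxel inside the target cell finds
its shell by bisection over the nested shell family (using per-shell radius
lookup tables), then its nearest angular grid point, and takes that PILR
value. Inverse mapping is hole-free and deterministic, unlike forward
splatting; linearity of the lookup makes morph(average) = average(morph)
exact, which the tests assert at 1e-6. Nuclear PILR rows land inside the
target nucleus by construction since shell index ≤ 32 is the nuclear
compartment.

Degenerate inputs: a target nucleus not contained in its target cell is an
error (tolerating only 0.5% stray boundary voxels from voxelization); mesh
points that fall outside the image sample 0 and are counted per cell.

## Organization statistics

- **Average location similarity**: Pearson correlation of flattened
  average PILRs; a zero-variance average is reported *missing with a
  reason*, never silently 0.
- **Clustering**: average linkage on Euclidean distances between
  similarity-profile rows. (Passing a correlation matrix directly to an
  average-linkage routine, as the source did, treats rows as feature
  vectors — the reading implemented here.)
- **Stereotypy** is the mean over *distinct unordered* within-structure
  cell pairs (self-correlations excluded). Whether ordered or distinct
  pairs were meant is immaterial — the mean is identical — but distinct
  pairs are what is implemented and tested.
- **Concordance** is the mean over all cross-structure cell pairs; it is
  symmetric by construction.
- **Per-map-point statistics** require a minimum number of cells per
  structure per bin (default 5); bins below it are missing, not zero.
- **Volume scaling**: total R² of structure volume on the five size
  metrics, and each metric's unique contribution as R²(full) −
  R²(without it). Collinear metrics trigger a warning since unique
  contributions are then not separable.

## Population comparison

- **Shape matching**: per query cell, the nearest baseline cell in 8D; the
  matched set is the unique flagged baseline cells plus the query cells.
  Ties break to the lowest baseline cell id (deterministic).
- **PCA + LDA axis**: PILRs are PCA-reduced to min(32, n) dimensions, then
  a two-class Fisher discriminant is fitted. When n ≤ 33 the within-class
  scatter in min(32, n) dimensions is necessarily singular; a small ridge
  (1e-6 of the mean diagonal) is applied with a warning rather than
  failing, because small-n structures are common in the comparisons this
  supports. The axis is unit-norm, oriented so the second population is
  positive, and z-scored by the **pooled** projection standard deviation
  (per-group vs pooled was unstated; pooled was chosen and is recorded
  here).
- **Flagging**: an entry must reach ρ = 0.03 in the earlier-stage
  (reference) matrix to be measurable, and a measurable entry is flagged
  when |Δ| ≥ ρ_diff = 0.02. The extremely-high-stereotypy exception (flags
  whose *relative* change is under 5%) is available as an off-by-default
  override.
- **TOC rule table** (the categories are defined in prose in the source;
  the full mapping is fixed here): m1_only = flagged(i1–m1) ∧
  ¬flagged(m1–m2); stepwise = flagged(i1–m1) ∧ flagged(m1–m2); m2_change =
  ¬flagged(i1–m1) ∧ (flagged(m1–m2) ∨ flagged(i2–m2)); otherwise
  no_change. Entries unmeasurable in all three comparisons are no_change
  with an `undetermined` annotation.
- **Stereotypy–concordance relationship**: per pair, `no_changes` when
  nothing changed; `co_timed` when every stage at which the concordance
  changed also saw a stereotypy change in at least one member (annotated
  when the first changes coincide); `independent` otherwise, including
  stereotypy-only changes.

## What the synthetic generator emulates — and what it does not

Cells are low-degree (l ≤ 4) SHE surfaces voxelized onto an isotropic
grid: an ellipsoid radial function projected onto l ≤ 4 plus zero-mean
random degree-1..4 perturbations with RMS amplitude `shape_noise_amplitude`
× base radius (capped below 0.3 to preserve star-convexity). The nucleus is
the same shape scaled by `nucleus_volume_fraction^(1/3)` — so the planted
volume ratio is exact in the continuum — optionally offset; offsets that
breach the cell boundary are rejected. Structure patterns plant punctate
(spheres by rejection sampling), reticular (random filament segments),
near-membrane shell, nuclear, and +x-polarized punctate (placement weights
`exp(bias · (x − x̄)/sd(x))`) geometries in their compartments.

Defaults were fixed once: base radius 12 voxels, aspect (1.4, 1.0, 0.9),
noise 0.05, nuclear volume fraction 0.25 (hiPS-like cells have large
nuclei), voxel edge 0.108333 µm. Real cells at this voxel size are ~100
voxels across; fixtures run at ~10–14 voxel radii purely for desk-scale
speed. Consequently a green test establishes *algorithmic* correctness
(round trips, oracle equivalence, planted-effect recovery) — not
biological conclusions, which require real data at full scale, nor
robustness to segmentation artifacts, optical anisotropy or touching
cells, which the generator does not emulate.

Fixture sizes in the statistical acceptance checks were chosen for
estimator stability, not tuned to outcomes:

- The shape-robustness check uses four deterministic size levels × 30
  cells (15 per structure per map point bin) with radius-3 blobs whose
  count scales with cell volume. Both choices matter: ~15-cell averages
  keep the sampling error of the between-structure correlation well below
  the 0.1 relative-Frobenius tolerance the check asserts, and scaling the
  count keeps the cytoplasmic *volume fraction* constant — a fixed object
  count would make coverage (and hence the similarity statistic) genuinely
  size-dependent, contradicting the shape-independent-placement premise
  the property is about.
- The planted-polarization check uses 60 puncta per cell (organelles such
  as mitochondria have dozens to hundreds of copies), giving each single
  cell a resolvable polarization signal at bias 1.0.
- The null LDA check runs at 1000 cells per group on synthetic PILR
  vectors: a two-class Fisher discriminant evaluated in-sample has an
  optimism of order sqrt(p(1/n₁+1/n₂)) (~1σ at 64+64 with p = 32, ~0.25σ
  at 1000+1000), so the ≤ 0.5σ null bound is a property of the estimator
  only at sizes where that optimism is small. At 64 + 64 the bound is
  *not* attainable in-sample; the check documents this by running the null
  at the larger n.

## Known limitations

- Radial SHE cannot represent non-star-convex cells faithfully; they are
  flagged and their coefficients are a least-squares compromise.
- Shell nesting (and hence morphing) assumes the nucleus is inside the
  cell and both are star-convex; strongly offset nuclei make the
  cytoplasmic shells only approximately nested.
- Intensity-mode PILRs are supported but all bundled statistics were
  exercised on binary (segmentation) PILRs.
- The LDA axis can pick up technical PILR differences rather than biology;
  deciding that requires inspection of the reconstructions, and the
  package deliberately surfaces it as a manual-review concern rather than
  automating a criterion that the source never specified.
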