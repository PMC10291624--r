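---
title: "Augmenting labeled plant point clouds: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Augmenting labeled plant point clouds: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantaug)
```

## The problem

Semantic plant-part segmentation networks for greenhouse phenotyping are
trained on labeled 3D point clouds of whole plants: a few hundred thousand
points each, with per-point position, surface normal, RGB color from a ring
of 15 cameras, a semantic class (soil base, support stick, stemwork, other
bio-structures, unclassified) and an instance label (soil base, stick, main
stem, or an individual leaf). Annotated plants are expensive, so training
sets are small — tens of plants — and data augmentation is the main lever
for generalization. `plantaug` implements the augmentation toolbox such a
pipeline needs: seven *global* methods that transform the whole cloud, and
three *local* methods that act on individual leaf instances, plus the leaf
geometry extraction the local methods depend on, per-class F1 evaluation,
and a synthetic plant generator that makes all of it testable without
access to scan data.

## The data model and normalization

A cloud is an `n × 3` position matrix (millimetres when raw), unit
normals, an `n × 45` camera-major color matrix in `[0, 1]`, and the two
label vectors. Before any augmentation the cloud is normalized:
x and y are zero-centered, z is shifted to start at 0, and **all three**
coordinates are divided by one isotropic factor `1 / (max z − min z)`, so z
spans exactly `[0, 1]`. A single height-based unit is used deliberately:
parameters of the positional augmentations (jitter sd, translation offsets,
leaf translation sd) are then all expressed as fractions of plant height,
so a jitter sd of 0.05 means 32.8 mm on a 657 mm plant. The scale and
offsets are stored in the cloud metadata, making the map invertible to
better than 1e-6 mm. `assemble_features()` stacks position, normal and the
45 color channels into the `n × 51` matrix a point-based network consumes.

Down-sampling to the fixed network input size (`n = 50,000` by default)
draws a uniform subset without replacement, *with* replacement only when a
preceding crop left fewer than the target — the fixed-size contract always
wins. `offline` mode is seeded and reproducible; `online` mode draws a
fresh subset per call, the behaviour used between training batches.

## Global augmentations

All operate on normalized clouds and none re-normalizes its output —
re-normalizing would cancel precisely the variation the method is meant to
inject.

* **Jitter** — i.i.d. Gaussian noise `N(0, σ_j)` per point per axis
  (default σ_j = 0.08, the strongest empirically useful level). Labels,
  normals and colors untouched.
* **Scaling** — `x' = η_x x, y' = η_y y, z' = z` with `η_x, η_y ~ U(a, b)`
  drawn *independently* per axis (default `U(0.5, 1.5)`); two symbols,
  two draws. z is fixed because height is the unit.
* **Rotation** — `R = Rz(γ) Ry(β) Rx(α)` with `γ ~ U(0°, 360°)` and
  `α, β ~ N(0, σ_r)` (one shared σ_r, default 1°), pivoted at the origin:
  after normalization that is the plant center at soil level, so a lean
  hinges at the base as a potted stem does. Normals are rotated by the
  same matrix; rotation is the only method with a defined action on
  normals, so the others leave them alone.
* **Translation** — one offset vector per cloud, components i.i.d.
  `U(a, b)` (default `U(−0.05, 0.05)`).
* **Cropping** — draw `φ ~ U(a, b)` (default `U(0, 0.15)`) and keep points
  inside the box `[(1−φ)·min, (1−φ)·max]` in x and y and `[0, (1−φ)·max]`
  in z, closed intervals; then re-down-sample online to the fixed size.
  This emulates plants that exceed the imaging volume.
* **Brightness** — one factor `η ~ U(a, b)` (default `U(0.5, 3.0)`)
  multiplying all 45 channels, **without clipping**: clipping would break
  the constant channel ratios a global illumination change produces, so
  the color invariant is relaxed from `[0, 1]` to `≥ 0` after this method.

## Leaf geometry

The local methods need, per leaf: a base point, a principal axis, and the
phyllotactic orientation. A full cylinder-fit reconstruction of the plant
architecture is unnecessary for that, so `plantaug` computes the
descriptors directly from the labels:

* **base point** — the leaf point nearest (Euclidean) to the main-stem
  point set, deterministic with lowest-index tie-break. This lands on the
  leaf side of the petiole–stem junction, within about a point spacing of
  the geometric attachment.
* **principal axis** — first principal component of the leaf's *stemwork*
  points (its petiole/rachis skeleton; falling back to all leaf points if
  fewer than 3 exist, which happens for sparse petioles near the top),
  sign-oriented base → centroid.
* **phyllotactic orientation** — the axis projected onto the horizontal
  plane and renormalized; a vertical axis raises a degenerate-projection
  error rather than returning an arbitrary direction.
* **phyllotactic angle** — the *directed* counterclockwise angle (viewed
  from +z) from the lower leaf's orientation to the upper one's, in
  `[0°, 360°)`. The directed convention matters: measured tomato
  phyllotaxis averages 185.1°, which a folded `[0°, 180°]` convention
  could not express.
* **ranks** — ascending base-point height, ties by leaf id.

Recovery quality is validated against the synthetic generator's ground
truth (ranks ≥ 99% adjacent-order agreement; axes within 10° for ≥ 95% of
leaves; median base error ≤ 2× the median point spacing at desk density).

## Local augmentations

* **Leaf translation** — an independent `ψ_z ~ N(0, σ_l)` per leaf added
  to that leaf's z only (default σ_l = 0.7). Offsets are independent
  across leaves, which occasionally detaches a leaf visually from the
  stem; that artifact is accepted rather than constrained away, since the
  method's purpose is internode-length diversity.
* **Leaf rotation** — about the vertical axis through the base point
  (`γ ~ U(−a, a)`, default a = 135°), changing the phyllotactic angle; or
  about the leaf's own principal axis through the base point
  (`θ ~ U(−b, b)`, default b = 50°, Rodrigues axis–angle), tilting the
  blade. Both are rigid on the leaf and the identity elsewhere; the base
  point (and, for the principal-axis variant, the whole axis line) is a
  fixed point.
* **Leaf crossover** — exchanges same-rank leaves among plants of one
  cultivar. Each round draws a rank present in ≥ 2 plants (without
  repetition across the `N_C` rounds, default `N_C = 4`), cuts that leaf
  from every plant holding it, and redistributes the cut leaves by a
  *uniform random derangement*, which guarantees no leaf returns to its
  own plant while conserving per-plant leaf counts. Each transplant is
  rigidly aligned to the leaf it replaces — rotated about the vertical
  axis so its phyllotactic orientation matches, then translated base to
  base; no scaling, since same-rank leaves are of comparable size.
  Positions and normals transform; colors travel with the leaf; the
  instance id is relabeled to the replaced leaf's. A final online
  down-sampling restores the fixed cloud size.

## The synthetic generator

`generate_plant()` emits a labeled tomato-like plant with known ground
truth: a soil disk, a vertical stem cylinder with a parallel support
stick, and L leaves — each a petiole/rachis tube (stemwork) carrying
elliptical leaflet patches (other bio) — attached at ranked heights.
Defaults encode the study conditions the package targets:

* leaf count drawn from `{6, 7, 8, 9}` with probabilities
  `(0.2, 0.3, 0.4, 0.1)` — mean 7.4, matching the reported training-set
  average; only the mean is reported, so the spread is a design choice of
  plausible width.
* adjacent-leaf azimuth increments i.i.d. `N(185.1°, 57.0°)` (mod 360),
  the measured phyllotaxis statistics. Real phyllotaxis is likely
  conditionally dependent between neighbouring ranks; the i.i.d. model is
  the same independence assumption the leaf-rotation augmentation makes.
* stem height `U(500, 700)` mm, stem radius 5 mm, petiole length
  ~130 mm, isotropic surface noise sd 0.6 mm, 15 per-camera brightness
  factors `1 + N(0, 0.08)` on a per-class base color, clipped to `[0, 1]`.

What it does *not* emulate: shape-from-silhouette occlusion artifacts,
curved rachises, fruit trusses, non-uniform point density with camera
distance, and real radiometry. Tests passing on synthetic plants therefore
validate the *transforms and estimators* (rigidity, alignment, recovery of
known geometry), not segmentation performance on real scans.

`points_per_plant` defaults to 100,000 (raw greenhouse scans average
~4×10⁵). The statistical validation runs use deliberately reduced desk
densities: 2,000 points/plant for the 500-plant phyllotaxis-recovery
experiment, 800 for the 1,000-plant leaf-count experiment, chosen as the
smallest sizes at which the geometric estimators are comfortably stable
(descriptor recovery degrades below roughly 1,000 points/plant as petiole
sampling becomes sparse).

## Numerical choices

* Down-sampling switches to replacement only when the source is smaller
  than the target, so the size contract survives aggressive crops.
* Crop bounds are closed intervals; an empty crop is an explicit error,
  never an empty cloud.
* Identity parameters (σ = 0, η = 1, φ = 0, γ = θ = 0, δ = 0) reproduce
  the input to 1e-12; rigid motions preserve pairwise distances to 1e-9.
* F1 uses the conservative zero-division convention (absent class → 0)
  and an unweighted macro average over the four evaluated classes;
  unclassifiable points are excluded from the tally.
* Every stochastic operation accepts an explicit seed and restores the
  caller's RNG state; pipeline runs derive per-file, per-step seeds from
  one global seed and log every drawn parameter value to the manifest, so
  any output can be re-derived bit-exactly.

## Known limitations

The base-point detector lands on the sampled leaf surface, so its error is
bounded below by the local point spacing and petiole radius; at very low
densities the first sampled petiole point can sit several millimetres up
the tube. Composition of several augmentations in one pipeline is
supported but goes beyond the one-method-at-a-time protocol the defaults
were tuned under. Crossover across cultivars is intentionally refused.

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_plant_config(points_per_plant = 5000)
plant <- generate_plant(cfg, seed = 1)
cloud <- normalize_cloud(plant$cloud)
leaf_descriptors(cloud)[, c("leaf_id", "rank", "base_z")]
plant_phyllotaxis(cloud)          # recovered angles, degrees
plant$truth$phyllotaxis_deg       # generator ground truth
out <- augment_crop(cloud, range = c(0, 0.15), n_target = 5000, seed = 2)
n_points(out)                     # exactly 5000
```
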