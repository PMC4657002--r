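---
title: "fascicle3d: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fascicle3d: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the science and the engineering judgement inside
`fascicle3d`: what each stage assumes, which tunable parameters matter and
why their defaults are what they are, what the synthetic generator does and
does not emulate, and where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## The problem

A peripheral nerve carries sensory, motor and mixed fascicles whose number
and arrangement change within millimetres. Reconnecting fascicles of equal
function during nerve repair requires a 3D map of the internal fascicular
topology, which can be built from serial histological cross sections —
provided the sections can be registered, the fascicle edges extracted, the
functional types recognised, and the contours stacked into surfaces. Four
fine fiducial threads ("position lines") embedded beside the specimen
appear in every section as dark, near-circular dots 12–15 px across and
serve as registration landmarks.

## Position-line recognition

A 15×15 window around a candidate blob is classified *circle-like* versus
*non-circular*. The window descriptor is the flattened grayscale patch,
min–max normalized per window (the classifier must respond to shape, not
absolute staining intensity). The LS-SVM solves one (n+1)×(n+1) linear
system; training is exact and deterministic, and every training window
keeps a dual coefficient.

* **Candidate prefilter.** Darkness threshold 0.45 plus connected-component
  area in [80, 230] px with a ≤ 22 px bounding box. The ideal disk areas for
  12–15 px diameters are [113, 177] px, but a rasterized 12 px disk can
  fall below 113; the window is deliberately wider so the prefilter is
  *provably weaker* than the classifier and never rejects a true landmark.
  Whatever slips through is rejected by the LS-SVM.
* **Kernel width.** `sigma2 = 20`, `gamma = 100` by default. For
  225-dimensional normalized windows, `sigma2 = 2` makes the Gram matrix
  nearly the identity and the decision surface brittle — that configuration
  is retained only as the *untuned baseline* against which genetic-algorithm
  tuning is compared.
* **GA tuning.** Real-coded, tournament selection (size 3), arithmetic
  crossover, Gaussian mutation (10 % of range), elitism of one, bounds
  `sigma2 ∈ [0.1, 50]`, `gamma ∈ [1, 1000]`. One individual of the initial
  population is seeded at the baseline (2, 100), so the tuned held-out error
  can never exceed it — a warm start, not an oracle.
* **Canonical labels.** The four centres are ordered counterclockwise (in
  standard orientation, x = column, y = −row) by angle around their
  centroid, starting at the smallest non-negative angle: S_a…S_d. Any fixed
  convention works; this one is rotation-stable for the mild (≤ 5°)
  misalignments the registration model expects.
* **Non-maximum suppression.** Radius 8 px, highest decision value wins,
  ties broken lexicographically by (row, col).

## Registration

The bilinear family `x' = a₀ + a₁x + a₂y + a₃xy` is exactly determined by
four control points in general position — precisely what four landmarks
give — and contains all translations, rotations about any centre, and
mild xy-coupled shears. Fitting is one 4×4 solve per output coordinate
(`rcond < 1e-12` raises a singular-geometry error). Warping uses backward
mapping with bilinear intensity interpolation (the standard artifact-free
convention; the source states no direction) and fills out-of-frame pixels
with the modal border colour. The reference section is the first by
default.

## Segmentation

Fascicle texture is granular: dark granules separated by unstained voids,
so neither plain edge detection nor region growing works on the raw pixels.

* **Foreground.** Grayscale → Gaussian blur (σ = 2.5 px, enough to fuse
  granules ~3 px apart into solid regions) → Otsu threshold (dark side) →
  drop components < 30 px → drop landmark-dot-sized compact components.
  The Otsu criterion is flat across an empty histogram gap; the
  implementation returns the plateau midpoint, which puts the cut halfway
  between the fascicle and background modes.
* **Dynamic clustering.** ISODATA-style: start with one cluster at the
  foreground centroid; each round reassigns points to their nearest centre
  and updates the centres, then — on alternating rounds — either splits any
  cluster whose *principal-axis* standard deviation exceeds
  `split_sigma = 23` px (two new centres offset ±0.5 sd along the axis) or
  merges centre pairs closer than `merge_dist = 34` px, closest first.
  Three details earned their keep: the spread test runs in the principal
  frame rather than the image axes (an axis-aligned test would make
  splitting a diagonal fascicle pair orientation-dependent); split and
  merge alternate with a full reassignment in between, because merging
  immediately after a split undoes it before the new centres can separate;
  and the fractional split offset lets spurious splits fall back together
  while genuinely bimodal clusters separate on reassignment. A final
  cleanup pass re-merges any centre pair left below `merge_dist` whatever
  phase the loop ended on. `split_sigma` sits between the principal spread
  of one fascicle (≈ r/2, and ≈ 0.9 r for a merged, elongated one) and that
  of two adjacent fascicles (≈ 1.15 r) at the generator's calibre
  r ≈ 22 px; `merge_dist` sits between the half-centroid spacing of the
  largest single fascicle (≈ 0.85 r_max ≈ 25 px, the distance at which two
  centres can lodge stably inside one fascicle) and the smallest true
  centre separation of adjacent fascicles (≈ 2r + 4 ≈ 46 px). Both are
  configuration-exposed for other scales.
* **Edge maps.** The contour is *not* driven by raw-texture gradients
  (granule edges trap it inside voids). Instead each cluster's
  neighbourhood of the blurred grayscale is re-thresholded locally — the
  local histogram is bimodal, so the local Otsu level sits at the blur
  midpoint and the mask boundary lands on the true edge — the boundary is
  regularized (blur σ `reg_sigma` then re-threshold at 0.5, a median-like
  smoothing that removes granule-scale raggedness without moving the
  boundary), holes are filled, and the gradient magnitude of the softly
  re-blurred mask (σ = 1.5) is the edge map, rescaled to a fixed peak
  source gradient of 0.5 so the GVF capture strength does not depend on
  the blur widths. `reg_sigma` defaults to 2.5 px ≈ one tenth of the
  default fascicle radius; the large-disk test fixture (radius 60) scales
  it accordingly to 6.
* **GVF.** Explicit diffusion `u ← u + dt(μ∇²u − |∇f|²(u − f_x))` with
  μ = 0.2, dt = 1 (the stability bound dt ≤ 1/(4μ) is enforced), 80
  iterations by default — a capture range of ≈ √(2·μ·n) ≈ 5.7 px, matched
  to the snake initialization below; fixtures with larger gaps raise
  `n_iter`.
* **Snake.** Semi-implicit evolution with a pre-factored cyclic
  pentadiagonal internal term (α = 0.1 tension, β = 0.5 rigidity,
  step 1.0), 100 vertices resampled to uniform arc length every iteration,
  stop when the largest vertex displacement drops below 0.1 px.
  Initialization is a circle at the cluster centre with radius 1.2× the
  cluster RMS radius (≈ 0.85× the fascicle radius for a disk, i.e. a few
  pixels inside the edge — within GVF capture). In **improved** mode only
  the component of the external force along the local contour normal
  (adjacent-vertex central difference, rotated 90°) is applied; the
  tangential component merely slides vertices along the curve, which the
  arc-length resampling undoes anyway, so dropping it cannot change the
  limit contour but removes wasted displacement from the stop criterion.
* **Energy bookkeeping.** The classical snake energy (tension + rigidity −
  edge-map value) decreases monotonically for an *enclosing* initial
  contour, the classical setting in which the snake shrinks onto the edge.
  An expanding snake must transiently *increase* its tension energy (its
  length grows before the external term engages), so the monotonicity
  property is stated — and tested — for the enclosing case.

## Functional typing

For a pixel (m, n) and scale r (default 11, minimum 5), the intensity
profile of length 2r+1 is sampled along 0°, 45°, 90° and 135° (diagonals by
integer steps, i.e. nearest-neighbour sampling). The first-order gradient
curve is the successive-difference sequence of the profile (2r values);
the second-order curve is the successive differences of the first (2r−1
values). This successive-difference reading is the unique simple rendering
consistent with the stated index ranges and with descriptors phrased in
terms of amplitudes and peak intervals; it is flagged here because the
source presents the formulas only pictorially.

Each curve yields three descriptors: the largest and second-largest value
of |curve| (duplicates allowed) and the mean index spacing of successive
peaks of |curve| (strict rise, plateaus credited to their leftmost index;
0 when fewer than two peaks). Peak spacing is computed on the magnitude
rather than the signed curve — amplitude sign is an artifact of scan
direction. With 4 + 4 curves × 3 descriptors × 3 RGB channels the feature
vector has exactly 72 entries for *every* r: the scale changes curve
lengths, not the descriptor count.

* **Sampling.** Uniform without replacement from the image interior
  (≥ r from every border), restricted to the segmentation foreground in
  pipeline use. In the pipeline, positions are drawn in the registered
  frame (where the contours live) but mapped back through the registration
  transform and rounded, so the texture is measured on *raw, unresampled*
  pixels: warp interpolation dilutes granule amplitudes by a per-section,
  subpixel-dependent factor that would otherwise leak section identity
  into the features.
* **Rough K-means.** k = 3 (the three functional classes; configurable).
  A point joins the lower approximation of its nearest centre unless a
  second centre is nearly as close (d₂/d₁ ≤ eps, default 1.15; `"auto"`
  sets eps from the 10 % quantile of the observed ratios), in which case it
  joins the upper approximations of all such centres. Centres update as
  `0.7·mean(lower) + 0.3·mean(upper∖lower)`. With eps = 0 the procedure
  *is* classical K-means from the same initialization — a tested
  reduction. Features are z-scored by default (amplitudes and intervals
  live on different scales), initial centres use k-means++ seeding, and a
  deterministic `nstart` (sub-seeded restarts, best within-cluster sum of
  squares wins) guards against bad local minima.
* **Cluster naming and votes.** Clusters are named by the mean grayscale
  of their member pixels — sensory stains darkest, motor lightest, mixed
  between. Each contour takes the majority vote of the lower-approximation
  labels inside it; a tie is labelled "mixed" (the only defensible call
  for an evenly split vote), and a contour containing no sample is
  "unknown".

## Reconstruction

Contours of consecutive registered sections are linked when their
rasterized Jaccard overlap reaches `jaccard_min`, greedily by descending
overlap with at most two children per parent and two parents per child;
1→2 patterns are splits, 2→1 merges. The default threshold is **0.2**, not
the 0.3 one might first choose: for an area-preserving two-into-one merge,
the parent–child overlap is geometrically capped near 0.35 (numerically
verified over child elongations 1.4–1.7), and detected-contour wobble of
±0.05 would put genuine merge links inside a 0.3 band, silently breaking
lineages. Non-corresponding fascicles overlap at ≈ 0, so the lower
threshold adds no spurious links.

Constant-type track segments become open tube meshes: rings resampled to
100 vertices, consistently oriented, rotationally aligned by the cyclic
shift minimizing summed vertex distance (prevents twisted lofts), and
triangulated with the shorter diagonal per quad. At a split the parent's
last ring is prepended to each child segment, at a merge the child's first
ring is appended to each parent, so junctions are stitched by the ordinary
lofting step and every mesh satisfies V − E + F = 0. Vertices carry x, y
in pixels and z in millimetres (section index × 0.5 mm); the mixed units
are recorded in the PLY header comment. Type colours: yellow sensory,
green motor, purple mixed.

Because tracks are constant-type chains, a type change along one anatomical
fascicle starts a new segment; the adjoining rings are shared, so the
geometry remains watertight across the change.

## The synthetic world

`generate_stack()` emulates exactly what the downstream stages assume and
nothing more:

* **Fascicles** are circles (radius ≈ 18–30 px at the default calibre 22),
  static across sections except at events. Fascicles that merge are
  equal-calibre circle pairs 4 px apart; a merged (or about-to-split)
  fascicle is an area-preserving ellipse of elongation 1.7 spanning the
  pair footprint. This triple of choices is forced jointly by three
  requirements: per-lineage masks static between consecutive sections
  (round-trip overlap ≥ 0.99), parent–child overlap above the link
  threshold, and a principal-axis spread that lets ISODATA separate the
  pair (≈ 26 px) but not split the child (≈ 21 px). A compact circular
  child cannot satisfy the overlap requirement at all.
* **Texture**: dark granules of radius 1–2 px scattered uniformly inside
  each fascicle at 72 % area coverage (granule counts are corrected for
  Poisson overlap so the configured coverage is the realized one), on an
  unstained background of 0.85 gray. Granule intensities: sensory 0.16,
  motor 0.50; mixed fascicles carry motor-like granules with a 20 % dark
  (sensory-like) subpopulation — light pixel groups mixed with a minority
  of dark ones, which is also what makes the class separable in the
  72-dimensional descriptor. The induced regional mean-gray ordering
  sensory < mixed < motor is a tested invariant. No texture statistics
  exist to copy from real specimens; these values are calibrated once to
  preserve the qualitative class structure and exposed in
  `texture_params`.
* **Misalignment**: per-section rotation ≤ 5° about the image centre,
  translation ≤ `misalignment_scale` px, plus an xy-coupling coefficient
  of magnitude ≤ `misalignment_scale`/(rows·cols) — so the bilinear family
  is the *correct* model to recover, and its fitted inverse (least squares
  on a 6×6 grid) is stored as ground truth alongside the forward map.
* **Landmarks**: four dots of configurable diameter 12–15 px near the
  corners, constant positions in the aligned frame (physical threads),
  drawn as true disks at the warped centres.
* **Not emulated**: staining artifacts, section tearing or folding,
  photorealistic H&E colour, intensity drift along the stack, fascicle
  shape irregularity. A green test therefore establishes algorithmic
  correctness on well-formed sections, not robustness to histological
  failure modes — the pipeline's gap handling (skipping sections whose
  landmark count is wrong) is the designed response to those.

Tests run the generator at 240×320 px rather than the nominal 1024×768 of
digitised sections purely for CPU budget; no tested property depends on
the raster size.

## Degenerate inputs and errors

Classed conditions are used throughout: wrong landmark counts
(`fascicle3d_detection_count_error`, carrying the count), singular control
point geometry, empty foreground, contour collapse (< 8 px perimeter),
GVF stability violations, border-clipped neighbourhoods, and invalid
configurations all raise distinct classes so pipelines can react
specifically; the orchestrator halts at the failing stage and preserves
completed artifacts.

## File formats

Stacks are ASCII PPM (P3), label maps and labelmap pages ASCII PGM (P2),
landmarks and transforms CSV, contours and types JSON, models ASCII PLY
(per-face colours) and OBJ+MTL, detector archives JSON. Everything is
plain text: the package runs without any binary image codec, and every
artifact is diffable.

## Known limitations

* Landmark centres are reported at integer pixel positions (the template
  centre); subpixel refinement would reduce the ≈ 0.4 px mean centre error
  further but is unnecessary for bilinear registration at this scale.
* The typing stage pools samples across all sections into one clustering;
  a stack whose sections contain only one functional class would still be
  forced into k = 3 clusters and rely on the darkness naming to stay
  sensible.
* Contour linking assumes registered sections; unregistered input degrades
  Jaccard overlaps silently.
* The tangential/normal force ratio at convergence reflects the angular
  roughness of the edge ridge; on strongly granular boundaries without
  mask regularization it can exceed the few-percent level even though the
  converged contours of the two snake modes coincide.
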