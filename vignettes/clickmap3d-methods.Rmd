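---
title: "clickmap3d: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clickmap3d: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: what is modelled,
which knobs matter, what the synthetic benchmark does and does not show, and
why the genuinely open design choices were made the way they were.

# The problem

Click-chemistry labelling (EdU incorporated during S phase, detected with a
fluorescent azide) plus tissue clearing and light-sheet microscopy yields 3D
intensity volumes of a whole mouse brain in which each proliferating nucleus
is a bright blob of roughly 10 µm diameter. Three computational stages turn
such volumes into biology: detecting each nucleus as one coordinate,
normalizing coordinates into a reference atlas, and counting per region. All
three are implemented here; everything upstream (clearing chemistry,
acquisition, stitching, deconvolution) and the estimation of deformable
registration are out of scope — deformation fields are inputs, produced by an
external registration tool or by the package's own simulator.

# Coordinate conventions

Physical coordinates are in µm. Voxel `i` (1-based, per axis) covers the
half-open interval `[(i-1)·s, i·s)`, so the atlas corner voxel contains the
physical origin `(0, 0, 0)` and `pointToVoxel()` is `floor(p/s) + 1` with an
NA "outside" sentinel instead of an error. Axes are abstract (`axis1..3`);
nothing assumes an anatomical ordering except the hemisphere midline, which
defaults to axis 3 and is configurable — reference atlas distributions do not
agree on axis order, so committing to one would only invite silent mistakes.

Transforms carry explicit direction tags. The chain consumed by
`applyChainToPoints()` follows the convention of point-based normalization
with registration toolkits: the *forward* (atlas → sample) affine is stored
and applied *inversely*; the *inverse* deformation field (a vector image on
the atlas grid, µm displacements) is applied *directly*, sampled by
trilinear interpolation. Points that land outside the atlas are clamped and
flagged, never dropped: `length(output) == length(input)` always, and the
flagged points surface later as the "unassigned" row of the region
statistics. Silent extrapolation of a deformation field hides registration
failure, which is why field sampling outside its support clamps to the edge
displacement and flags too.

# Detection

`subtractBackground()` is a rolling-ball-style high-pass: the background is a
wide Gaussian blur (sigma must exceed the nuclear radius; a warning fires
otherwise) subtracted and clipped at zero. `downsampleVolume()` reduces the
native acquisition resolution (0.334 µm) to the working resolution
(3.65 µm) with block means when the ratio is integer (mass-conserving) and
Gaussian-prefiltered trilinear interpolation otherwise (said in a message).

Voxel classification uses a random forest (`ranger`, 100 trees, fixed seed,
single-threaded for determinism) over 10 features: raw intensity plus
Gaussian smoothing, gradient magnitude and Laplacian at scales
{0.7, 1.6, 3.5} × voxel spacing. The feature set of the interactive tool the
workflow replaces is unpublished, so this standard multi-scale surrogate is
used; a plain threshold mode (fixed value or Otsu) exists as a fallback and
is flagged in the model's provenance.

Component filtering applies the three-voxel rule: connected components
(26-connectivity by default; 6/18 configurable and recorded) smaller than
`min_voxels = 3` are discarded as noise. The minimum is deliberately *not*
rescaled with voxel size — the rule was applied at the working resolution
during the resolution reduction, so it is a property of the instrument
pipeline, not of geometry.

## Splitting touching nuclei

At 3.65 µm a 10-µm nucleus spans ~2.7 voxels, and a touching pair is ~3
voxels apart. The classical recipe — seeds from h-maxima of the
native-resolution Euclidean distance transform (EDT) — saturates there: the
EDT is so quantized that distinct maxima merge regardless of h. It is kept
as `method = "hmaxima"` (h = 0.3 × expected radius) because it is adequate
and cheap when nuclei span many voxels, but the default `method =
"subvoxel"` refines first:

1. the denoised intensity (Gaussian, 1 µm) is trilinearly upsampled 3×;
2. each component is re-thresholded at 0.5 × the *single-nucleus* peak — the
   full-width-half-maximum surface of a blurred sphere recovers the true
   sphere boundary. The single-nucleus peak is the median peak over the
   smaller half of the components, because overlapping PSFs raise peaks
   inside fused blobs and a per-component reference would swallow whole
   clusters;
3. watershed markers are the "cores" `EDT ≥ 0.8 × min(component EDT max,
   single-nucleus EDT max)` — morphological erosion by ~80 % of the nuclear
   radius, which separates touching pairs whose waist the h-maxima miss;
4. tight 3- and 4-clusters (near-regular simplexes) can still erode to one
   central core; for components where intensity h-maxima (h = 0.12 × peak)
   *and* an interior-volume bound (how many single-nucleus interiors fit,
   with the single volume self-calibrated as the median over single-core
   components) both indicate more nuclei than the EDT found, the brightest
   that-many intensity islands become the markers instead:
   `count = max(EDTcores, min(intensityIslands, volumeBound))`;
5. marker-controlled watershed floods the interior on descending EDT;
   centroids are intensity-weighted means on the fine grid. A component
   whose interior vanishes entirely (possible for very dim blobs) keeps one
   instance computed at native resolution, so no filtered component is ever
   lost.

Every threshold in this scheme is relative to self-calibrated quantities
(peaks, EDT maxima, interior volumes), not absolute intensities, so it
survives global brightness changes. The tunables and defaults:
`upsample = 3`, `interior_frac = 0.5`, `seed_frac = 0.8`,
`denoise_sigma_um = 1`, `expected_radius_um = 5` (a 10-µm nucleus; used only
for the orphan fallback volume and the h-maxima path).

## Validation metrics

The workflow is validated twice, and the two accuracies answer different
questions, so they are computed differently (no canonical formulas exist for
them; these definitions are this package's):

* **signal/noise accuracy** — was each ground-truth object given the right
  class by classification plus component filtering? A nucleus is correct if
  *any* predicted centre lies within one nuclear diameter (members of an
  under-split cluster were classified signal, merely not counted apart); a
  speckle is correct if *no* predicted centre lies within half a diameter.
* **count accuracy** — were nuclei counted apart correctly? Predictions are
  matched one-to-one to true centres (greedy on ascending distance, within
  one diameter) and a cluster is correct only if its matched count equals
  its true size exactly.

# Synthetic data: what it emulates, and what it does not

The generator produces: bilaterally symmetric toy atlases with an
Allen-style three-level ontology, a ventricle region and an adjacent
caudoputamen-like shell (so SVZ-style annotation is exercisable); nuclei of
radius 5 µm placed region-by-region at prescribed densities (Poisson counts,
mean = density × region volume), organized in clusters of 1–4 laid out as
randomly rotated regular simplexes with edge 1.0–1.5 diameters (touching to
nearly touching — the hard case for counting) under a hard-core non-overlap
constraint between clusters; rendering as antialiased spheres blurred by an
isotropic Gaussian PSF with Poisson photon noise and Gaussian read noise;
single-voxel speckle injection at known positions; a smooth
anatomy-correlated autofluorescence channel with a bright one-voxel surface
rim (emulating the cortical-surface artifact of cleared brains); and known
affine + smooth nonlinear transform chains whose forward map is recovered
from the stored inverse field by fixed-point iteration, so
normalize(forward(x)) round-trips by construction.

It does **not** emulate: anisotropic or depth-varying PSFs, stitching seams,
vasculature or other structured autofluorescence, intensity inhomogeneity
across nuclei beyond Poisson statistics, chromatic shifts between channels,
or real deformable registration error. Passing the benchmark therefore shows
the *algorithmic* chain (classification, filtering, splitting, transforming,
counting) is correct under a realistic camera model — it does not certify
performance on any particular microscope's artifacts.

## Benchmark conditions

Fixed once, in `benchmarkConfig()`: toy atlas 30³ voxels at 10 µm (300 µm
box, ~0.008 mm³ brain); densities 40,000 / mm³ in the caudoputamen-like
leaves and 18,000 / mm³ in the other non-ventricular leaves (about 2.2×
enrichment; no quantitative per-region densities are established for this
assay, so these are this package's choice of a realistic, SVZ-enriched
regime — they are *not* literature values); uniform cluster-size mix over 1–4; rendering
at 3.65 µm with PSF 1.5 µm, photon scale 80 and read noise 2; 150 speckles
per volume at amplitude 60 (nucleus-level brightness). Five volumes are
generated per run (≥ 200 clusters on the held-out side), the classifier is
trained on ground-truth-derived sparse labels (2,500 foreground, 4,000
background plus every speckle) from the first two, and both accuracies are
pooled over the three held-out volumes. The acceptance suite requires count
accuracy ≥ 0.878 and signal/noise accuracy ≥ 0.988, the lower ends of the
validated ranges. One full run takes a couple of minutes on one CPU; these
problem sizes (82³ rendered voxels, ~170 nuclei per volume) were chosen so
the whole suite stays desk-scale.

# Registration

`estimateAffine()` minimizes the mean-squared intensity difference with
Nelder–Mead over 12 parameters (Euler rotations, per-axis scales, shears,
translation), initialized from intensity moments (centre of mass and
principal axes), on a two-level coarse-to-fine schedule with strided
sampling on grids larger than 48³. MSE was chosen over mutual information
because the package aligns like-to-like (autofluorescence to an
autofluorescence-style template); MI and pyramids beyond two levels are
out of scope. If refinement fails to beat the initialization the init is
returned with a warning and `improved = FALSE`. The estimate is returned in
the atlas → sample direction so it plugs directly into the inverse-use
convention.

# Atlas annotations

* **SVZ layer**: parent-region voxels face-adjacent (6-connectivity by
  default — the most conservative reading of "a layer of single pixels";
  18/26 widen the layer and are opt-in) to the adjacent region are
  relabelled with the reserved custom ID (default 5, collision-checked
  against the ontology — on collision the tool refuses rather than
  renumbering silently). Both reporting semantics exist because both are
  used in practice: `exclude_from_parent = TRUE` makes the layer its own
  top-level region; `FALSE` keeps it a child of the parent so top-level
  counts still include it.
* **Consensus region**: voxels positive in ≥ `min_votes` of N replicate
  masks (default 4 of 7) get the custom ID; `exclude_from_regions = TRUE`
  removes them from their original regions, `FALSE` keeps labels intact and
  attaches the mask so counts can be reported both ways. Only in-brain
  voxels are eligible (label 0 means outside the brain and must stay so).
* **Hemispheres**: nonzero labels on the lower-index half of the midline
  axis gain +1,000,000,000 (stored as doubles; the offset exceeds any
   32-bit label), the ontology is duplicated with "left "/"right " name
  prefixes, and on an odd-length axis the midplane column goes to the right
  side with a message.

All annotations are pure relabelings: the voxel grid never changes shape.

# Quantification choices

"Ratio of positive nuclei" is implemented as a density, nuclei / mm³ —
count divided by region volume; a per-voxel variant would differ only by
a constant factor. Collision
ratios bin points into absolute half-open grids anchored at the atlas
origin (no shift is searched), so two points 5 µm apart may or may not
collide at 10 µm depending on where they sit — exactly the behaviour of
voxel assignment. Monotonicity of the overall collision ratio in voxel size
holds statistically (the 10/25/50 µm grids are not nested, so pathological
single-pair counterexamples exist) and is asserted on random point sets.

Colocalization matches one-to-one, greedily on ascending distance with ties
broken by index order, strictly below the 5 µm threshold ("less than"
means less than). Greedy maximal matching equals exhaustive
maximum-cardinality matching in the sparse regime the assay lives in
(match radius well below inter-nucleus spacing) and is verified against a
brute-force oracle there; in artificially dense configurations greedy can
be smaller, which is the price of its determinism and speed. Both possible
denominators for the double-positive ratio (all marker-positive nuclei vs
per-region marker-positive nuclei) are emitted, labelled.

Points with region ID 0 are reported as "unassigned", excluded from
fractions, never dropped. `hemisphereCompare()` pairs rows by base ID
arithmetic and flags one-sided regions; an empty right side yields an
infinite ratio rather than an error.

# Degenerate inputs and numerical notes

Empty masks detect to empty sets; empty point sets quantify to zero counts
without division errors (densities are 0, fractions 0). Affine inversion
requires |det| > 1e-12; chain composition is verified associative to
machine precision. The ground-truth transform generator enforces an
invertibility envelope (|rotation| ≤ 20°, scale ∈ [0.8, 1.25], warp ≤ 5
voxels) and scales Gaussian-filtered noise so the *maximum* displacement
equals the requested amplitude; fixed-point inversion uses 20 iterations,
far past convergence for that envelope. All randomness flows through one
integer seed per call (`withSeed` saves and restores the global RNG state);
the pipeline derives per-stage seeds from the config seed by fixed offsets
so any stage can be rerun in isolation.

# Interfaces

File formats: NRRD (raw/gzip, minimal reader-writer built in), multi-page
32-bit TIFF with a JSON sidecar for spacing and intensity scale (TIFF
itself stores neither), 4D NIfTI for deformation fields, a 12-number text
format with a direction header for affines, structure-graph JSON for
ontologies (validated for duplicate IDs and orphan parents on both read and
write), CSV for point tables. The package is a library: `runPipeline()`
(YAML config, provenance JSON with config hash, seed and per-stage
input/output counts) and `runBenchmark()` are the orchestration entry
points, and together with these functions the vignette is the user
interface — no shell executable is shipped.

# Known limitations

Detection assumes roughly spherical, roughly equal-sized nuclei; elongated
or strongly size-dispersed nuclei would need the splitter's calibration
rethought. The affine estimator is local (moments + simplex refinement) and
can miss under large rotations (> ~15°) or poor overlap; real pipelines
should initialize from a rigid pre-alignment. The consensus annotation
treats masks as already atlas-aligned. The benchmark's camera model is
simple, as discussed above; and the greedy matcher is maximal, not maximum,
off the sparse regime.
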