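---
title: "Methods: bone morphometry and intracortical porosity with poroct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bone morphometry and intracortical porosity with poroct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poroct)
```

## The measurement problem

High-resolution microCT of rodent long bones yields isotropic grayscale
volumes (1–2 µm voxels) in which mineralized bone is bright and everything
else — marrow, soft tissue, and the voids inside the cortex — is dark. Two
families of indices are extracted from such scans:

* **Macrostructure.** For trabecular bone: the bone volume fraction BV/TV,
  trabecular thickness Tb.Th, separation Tb.Sp, and number Tb.N. For the
  cortical shaft: the wall thickness Ct.Th and the outer diameter Ct.OD.
* **Intracortical microstructure.** The cortical porosity split into its
  two biological compartments: *vascular canals* (quasi-longitudinal
  channels carrying vessels) and *osteocyte lacunae* (small ellipsoidal
  cavities each housing one osteocyte). The split is purely morphometric —
  a volume classification of pore connected components.

`poroct` implements both chains end to end, plus the statistical decision
flow used to compare small animal groups, and — because real scans of this
kind are rarely shareable — a synthetic phantom generator with analytic
ground truth and a scan simulator that reproduces the partial-volume
behaviour of coarser acquisitions. Every stage of the pipeline is therefore
testable at desk scale.

## Segmentation chain

**Thresholding.** Trabecular volumes are binarized with Otsu's criterion:
the threshold maximizing the between-class variance of a 256-bin histogram
over the observed intensity range, computed on the full 3D dataset (not per
slice — per-slice thresholds would make volume metrics inconsistent across
slices). For cortical pore extraction a *global manual* threshold is the
norm in practice, so the pipeline accepts a fixed threshold; on phantoms,
where the phase intensities are known, the midpoint of the two levels is
used. `otsu_threshold()` is verified in the test suite against a
brute-force search over every candidate split.

**Morphology.** Closing uses a Euclidean ball, implemented exactly through
two distance transforms (dilation keeps voxels within *r* of the
foreground; erosion keeps voxels farther than *r* from the dilated
background), with padding so border-touching structures are not clipped.
Despeckling removes connected components of a phase below (or above) a
volume threshold; foreground components use 26-connectivity and background
holes 6-connectivity, the standard complementary pair (the exact
connectivity used by commercial tools is unpublished; this choice is
documented here as the package's surrogate). Survival is inclusive: a
component of exactly 280 µm³ survives a "remove below 280 µm³" despeckle,
i.e. 35 voxels at 2 µm and 280 voxels at 1 µm.

**Cortical ROI.** The analysis region for the cortex is the *solid
annulus*: the largest bone component, closed with a ball of 10 µm radius
(default — larger than any lacuna, far smaller than the marrow radius, so
it bridges intracortical pores without annexing the marrow), then per-slice
hole filling of every enclosed cavity except the largest one per slice,
which is taken to be the marrow. Consequences used throughout: the mean
local thickness of the ROI is Ct.Th *unaffected by porosity*, and
`ROI & !bone` is exactly the intracortical pore set. The construction
assumes an annular topology in every slice and raises an error otherwise.

## Local thickness

Thickness is model-independent in the maximal-sphere sense: the value at a
voxel is the diameter of the largest sphere that fits entirely inside the
phase and contains that voxel. The implementation computes the exact
Euclidean distance transform and then performs sphere-openings at a
descending sequence of radii taken from the distinct squared distances
present; a voxel's thickness is twice the largest radius at which it
survives the opening. With the full radius set this is *exactly* the
maximal-sphere definition (the suite checks equality against an exhaustive
oracle on small grids); for large volumes the radius set is thinned so
consecutive radii differ by at most half a voxel, bounding the error at one
voxel in diameter. The opening formulation was chosen over distance-ridge
sphere painting because its cost is O(voxels × radii) with early
termination — on a near-uniform cortical wall it finishes after a handful
of radii — and because its exactness is directly testable.

Two border conventions are exposed. With `border = "background"` (default)
the dataset face counts as background and spheres are clipped there. With
`border = "extend"` the face is treated as a cut through a continuing
structure. The distinction matters: a 180 µm shaft segment with a 60 µm
wall loses several percent of Ct.Th under the background convention because
every voxel within a sphere radius of the cut ends sees a clipped sphere.
`ct_thickness()` and the pore-diameter computation therefore use
`"extend"`; trabecular metrics use the default.

Mean thicknesses are volume-weighted (every foreground voxel contributes
its local value), which keeps the reported mean consistent with the
thickness distribution histogram (binned at one voxel by default). Tb.N
uses the plate-model-free convention Tb.N = (BV/TV)/Tb.Th, reported per mm.

## Outer diameter

Ct.OD is computed per 2D slice of the marrow-filled shaft from the
plate-model relation printed with the original analysis protocol:
Ct.OD = 2/(surface/volume) = 2A/P, the `as_printed` variant. For an ideal
circular section 2A/P equals the *radius*, so a `cylinder_corrected`
variant 4A/P (the diameter of the equivalent circle) is computed alongside
and both are reported; which of the two the commercial implementation used
cannot be determined from the available text, so the printed formula is the
default and the geometric discrepancy is left visible. The perimeter P is a
marching-squares contour length with orientation-calibrated segment weights
(0.948 per axis step, 1.340 per diagonal step); naive segment lengths
overestimate the perimeter of a digitized circle by ~4–5%, while the
calibrated weights are accurate to well under 1% (the suite checks a
digitized disc).

## Pore classification

Pores are the ROI minus bone. Components (26-connectivity) are classified
by volume with half-open boundaries so the classes partition:

* `< 280 µm³` — speckle noise, removed;
* `[280, 4000) µm³` — osteocyte lacunae;
* `>= 4000 µm³` — vascular canals.

The wording of the original despeckle cascade overlaps at exactly
4000 µm³; a partition is required, and 4000 µm³ is assigned to the canal
class. Per-class metrics use the solid ROI volume (pores included) as the
Ct.TV denominator, since densities are "per mm³ of cortex"; the denominator
is not stated explicitly in the source protocol, and this choice is the
package's. Pore diameters are volume-weighted mean local thicknesses of
each component (the structure-thickness convention); equivalent-sphere
diameters are stored alongside for comparison. Components touching the
volume border are *included* by default (canals crossing the dataset ends
are real structures); an `exclude_border` option exists. The despeckle
sensitivity sweep re-runs the classification over lower bounds
{150, 220, 250, 280, 310, 340, 450, 550} µm³ with the canal bound fixed,
tabulating lacunar count, volume, diameter and porosity; lacuna counts are
non-increasing in the bound by construction.

## Phantoms and ground truth

The cortical phantom is a hollow tube (bone bright, everything else dark)
pierced by straight cylindrical canals tilted at most 10° from the shaft
axis and by non-touching triaxial ellipsoidal lacunae with random
orientation. Structures are placed by rejection sampling with a 4 µm
clearance to each other and to the wall surfaces, so rasterized components
never merge and the component-count ground truth is exact; impossible
packings raise an error after bounded retries. Gray levels carry partial
volume: every voxel is sampled at 4×4×4 subvoxel points and the bone
fraction maps linearly to intensity (4× rather than 2× because the coarser
quantization, combined with a ≥-half binarization cut, systematically
assigns exactly-half-filled boundary voxels to bone and biases pore volumes
low by several percent). All randomness is scoped to the spec's seed:
identical specs render bit-identical volumes.

Analytic truth accompanies every phantom: wall thickness and outer diameter;
per-canal volume πr²L·sec(tilt); per-lacuna volume 4/3·πabc; class
porosities over the analytic wall volume π(r₀² − rᵢ²)L.

The default spec is a desk-scale shaft — 280 µm outer diameter, 60 µm wall,
180 µm length at 1 µm voxels (~14.5M voxels) — carrying 10 canals of
diameter ~N(12, 3²) µm truncated to [7, 20] and 200 lacunae of volume
~N(600, 200²) µm³ truncated to [320, 3500] with aspect ratios 1:0.65:0.35.
Canal diameters and lacuna volumes are order-of-magnitude choices within
the ranges reported for murine cortex (canals ~5–30 µm, lacunae
~100–4000 µm³); the truncation bounds keep every structure unambiguously
inside its volume class even after ±5% rasterization error, because the
recovery test asserts *exact* counts. A real mouse tibia is ~1.2–1.5 mm
across with a ~200 µm cortex; the scaled-down shaft keeps the full pipeline
(including thickness transforms) in the tens of seconds on one CPU while
preserving every geometric relation the pipeline exercises — this is a
deliberate problem-size choice, stated here once.

Trabecular phantoms are plate lattices (slabs perpendicular to the slice
axis, period p, thickness t, so BV/TV = t/p exactly when the domain is a
whole number of periods), rod lattices (cylinders along all three axes on a
cubic lattice, with the inclusion–exclusion cell volume
3πr²a − 16r³ + 8(2 − √2)r³ as truth), or a mixed plate-plus-rod structure.

## Scan simulation

`simulate_scan()` chains Gaussian blur (PSF given as FWHM; default 2× the
target voxel, a typical detector blur scale), block-average downsampling by
the integer voxel ratio (the partial-volume step; trailing voxels that do
not fill a block are dropped), and additive Gaussian noise with its own
seed. Blur and averaging preserve the mean intensity exactly; with unit
factor and zero blur/noise the operation is the identity. What the model
deliberately omits: polychromatic beam hardening, ring artefacts, detector
afterglow, and reconstruction filters. Passing the resolution-bias test on
these phantoms therefore demonstrates the *partial-volume mechanism*, not
full scanner realism — on real scans additional artefacts can only worsen
thin-structure detection.

The resolution experiment pairs, per seed, a fine scan (1 µm, FWHM 2 µm)
and a coarse scan (2 µm, FWHM 4 µm) of the same phantom, runs the cortical
pipeline on both with one common global threshold, and reports per-metric
paired comparisons with the relative difference of the coarse scan against
the fine scan. On a thin-canal phantom (8 canals of ~6 µm diameter — each
still above the 4000 µm³ canal class bound thanks to the 200 µm length —
plus 50 in-class lacunae) the coarse scan fragments and loses canals:
vascular canal density and porosity drop strictly, for every seed, and the
canal diameter reads several percent thinner, reproducing qualitatively the
published direction and mechanism of the voxel-size bias.

## Statistics

`compare_groups()` implements the small-n decision flow: Shapiro–Wilk on
each group at α = 0.05; if both pass, an F test decides between the pooled
and the Welch two-tailed t test; otherwise Levene's test (classical,
centered on the mean, via `car::leveneTest`) is reported for variances and
a Kruskal–Wallis test is used — retained under that name even for k = 2
groups, where it is equivalent to a Mann–Whitney test up to tie handling
(midranks, the R default). A two-sided Dixon Q screen (r10 ratio, classical
α = 0.05 critical table for n = 3..30) is reported per group but never
removes observations. No multiple-testing correction is applied, matching
the source protocol. Under the null (two normal n = 8 samples) the whole
flow holds its empirical type-I error within [0.035, 0.065] at 2000
replicates — the mixture of a level-α t branch (~90% of draws) and a
level-≈α Kruskal–Wallis branch stays close to nominal.

Effect descriptors follow the reporting conventions of the field:
`percent_difference()` and `fold_change()` round half away from zero to one
decimal and satisfy fold = 1 + pct/100 before rounding;
`paired_resolution_compare()` reports 100·(mean₂ − mean₁)/mean₁ with a
paired t test (flagged degenerate for constant differences); `homa_ir()` is
(FBG × FPI)/405 with glucose in mg/dL and insulin in mU/L.

## Numerical choices and degenerate inputs

* Distance transforms are exact squared-Euclidean (Felzenszwalb–Huttenlocher
  lower envelopes), so all sphere-fit tests are integer-exact; the strict
  sphere {x : |x − c|² ≤ r² − 1} is used so a maximal sphere never contains
  a background voxel centre.
* Otsu requires at least two distinct intensities and errors on constant
  images; ties between equal-variance splits resolve to the lowest
  threshold.
* `despeckle(min_volume = 0)` and `despeckle_upper(Inf)` are identities;
  closing is idempotent and extensive (tested as properties).
* Empty pore classes report zero porosity and density and an `NA` diameter
  rather than an error; paired comparisons drop `NA`-paired specimens and
  flag constant differences instead of dividing by zero.
* `align_to_axis()` (optional helper) refuses near-spherical objects
  (principal-axis ratio < 1.05) with a warning and returns the volume
  unchanged.
* Stack I/O is lossless for integer volumes (16-bit TIFF); the voxel size
  travels in a YAML sidecar and is never inferred from TIFF resolution
  tags, which are unreliable in CT exports.

## What the tests do and do not show

The phantom suite demonstrates correctness of the operators (against
exhaustive oracles), exact conservation and monotonicity properties of the
classification, recovery of known geometry through the full pipeline, and
the direction and mechanism of the resolution bias. It does not calibrate
the pipeline against real mouse tibiae: real cortical bone has canal
networks with branching, finite canal length, mineral-density gradients,
and unsegmentable (sub-resolution) lacunae, none of which the phantoms
emulate. Canalicular porosity is below both working resolutions and is
explicitly out of scope, as is canal-network topology.
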