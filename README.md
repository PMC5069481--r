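# poroct

Quantitative 3D bone morphometry for high-resolution microCT (HR-microCT),
in R. The package targets the two analyses that small-animal bone studies
run on 1–2 µm isotropic scans of long bones:

* **Macrostructure** — trabecular indices (BV/TV, Tb.Th, Tb.Sp, Tb.N and
  the thickness distribution) from Otsu segmentation, ball closing and
  double despeckling; cortical wall thickness **Ct.Th** (mean maximal-sphere
  thickness of an automatically fitted, pore-free cortical ROI) and outer
  diameter **Ct.OD** from per-slice plate-model geometry,
  Ct.OD = 2/(surface/volume) = 2A/P (with a cylinder-corrected 4A/P variant
  reported alongside).
* **Intracortical porosity** — pores = ROI ∖ bone, despeckled below
  280 µm³ (35 voxels at 2 µm, 280 voxels at 1 µm), then split by connected
  component volume into **osteocyte lacunae** ([280, 4000) µm³) and
  **vascular canals** (≥ 4000 µm³), each class reported as porosity
  (Ca.V/Ct.TV, Lc.V/Ct.TV, %), density (N.Ca/Ct.TV, N.Lc/Ct.TV, #/mm³) and
  diameter (Ca.D, Lc.D, µm, volume-weighted local thickness), plus a
  despeckle sensitivity sweep over {150…550} µm³.

Thickness everywhere is the model-independent maximal-sphere (local
thickness) definition — thickness at a voxel is the diameter of the largest
inscribed sphere containing it — computed from exact Euclidean distance
transforms.

Because scans of this kind are rarely shareable, the package also ships a
**phantom generator** (hollow cortical shafts with tilted cylindrical
canals and ellipsoidal lacunae; trabecular plate/rod lattices — all with
analytic ground truth and partial-volume gray levels) and a **scan
simulator** (Gaussian PSF blur, block-average downsampling, additive
noise). Together they reproduce, seed by seed, the known voxel-size bias:
at 2 µm the pipeline fragments and misses thin canals, so vascular canal
density and porosity are systematically underestimated relative to 1 µm.

A statistics module implements the small-n group-comparison decision flow
(Shapiro–Wilk → F test / Levene → pooled/Welch t or Kruskal–Wallis, Dixon
outlier screen reported non-destructively), paired resolution comparisons
with relative differences, HOMA-IR = (FBG × FPI)/405, percent differences
and fold changes as reported in the field.

## Worked example

Generate a small cortical phantom (140 µm shaft, 40 µm wall, 3 canals of
~11 µm diameter, 15 lacunae of ~450 µm³) and run the full cortical
pipeline:

```r
library(poroct)
spec <- cortical_phantom_spec(
  outer_diameter_um = 140, wall_thickness_um = 40, length_um = 80,
  canal_count = 3, canal_diameter_um = c(11, 0.5),
  canal_diameter_range_um = c(10, 12),
  lacuna_count = 15, lacuna_volume_um3 = c(450, 100),
  lacuna_volume_range_um3 = c(320, 600),
  render_voxel_um = 1, rng_seed = 42)
ph <- make_cortical_phantom(spec)
ph$volume
#> <voxel_volume> 144 x 144 x 80 voxels @ 1 um (0.144 x 0.144 x 0.08 mm)
#>  provenance: cortical phantom seed=42 voxel=1um

report <- run_cortical_pipeline(ph$volume, bone_threshold = 110)
report
#> Ct.Th 40.31 um   Ct.OD 70.31 um (as_printed)   Ct.TV 0.00101 mm^3
#> canal: porosity 2.2901%, density 2978.1 /mm^3, diameter 10.75 um (n = 3)
#> lacuna: porosity 0.6469%, density 14890.4 /mm^3, diameter 5.02 um (n = 15)
```

Reading the output against the phantom's analytic truth: Ct.Th recovers
the 40 µm wall within a voxel; the `as_printed` Ct.OD variant returns the
shaft *radius* for a circular section (70 µm for the 140 µm tube — the
cylinder-corrected variant in `report$cortical` reads 140 µm); all 3
canals and all 15 lacunae are found, and the class porosities (2.29% and
0.65%) sit within ~2% relative of the analytic truths (2.33% and 0.67%).
`report$pores` holds the per-component table (volume, class, diameter).

The same objects drive the other entry points: `run_trabecular_pipeline()`
for BV/TV/Tb.* on trabecular stacks or lattice phantoms,
`despeckle_sensitivity()` for the despeckle sweep,
`run_resolution_experiment()` for the paired 1 µm vs 2 µm protocol,
`analyze_cortical()` to write a CSV report directory for a stack on disk,
and `compare_groups()` / `paired_resolution_compare()` for the statistics.
A thin command-line front-end lives at `inst/cli/poroct.R`
(`Rscript poroct.R phantom|analyze-cortical|analyze-trabecular|resolution …`).

Stacks are multipage 16-bit grayscale TIFFs with a YAML sidecar carrying
`voxel_size_um` (never inferred from TIFF tags); integer volumes round-trip
bit-exactly through `write_stack()`/`read_stack()`.

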