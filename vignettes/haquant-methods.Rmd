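---
title: "Quantifying hyaluronan matrix architecture: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hyaluronan matrix architecture: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haquant)
```

## The measurement problem

After focal brain ischemia, reactive astrocytes assemble a dense
hyaluronan-rich extracellular matrix around the lesion — the glial scar.
In fluorescence micrographs the hyaluronan is visualized with a
biotinylated hyaluronic-acid binding probe (HABP), newborn astrocytes with
the proteoglycan marker Thbs4, and the hyaluronan receptor CD44 reports
internalization and degradation. Three architectural readouts summarize
how this matrix changes across post-injury time points and brain regions:

* **Cable length** — the hyaluronan signal is segmented, thinned to
  one-pixel centerlines, and each connected skeleton is summarized by its
  *longest shortest path* (geodesic diameter), a proxy for the length of
  the hyaluronan cable. Populations of cable lengths are compared across
  conditions as cumulative distributions.
* **Interconnectivity** — the box-counting fractal dimension of the
  skeletonized matrix mask.
* **Compartmental hyaluronan** — per astrocyte, hyaluronan area inside the
  cell, within a 1 µm band around the membrane (hyaluronan is synthesized
  at the membrane), and outside all cells; plus counts of intracellular
  HABP puncta and a CD44-internalization flag per cell.

`haquant` implements this pipeline end to end, together with radial
core-to-penumbra intensity profiles of lesion markers, Kruskal–Wallis
comparison of grouped cable lengths, and 2^-ΔΔCt semi-quantification for
the accompanying qPCR tables.

No reference imaging dataset is deposited alongside the original
analyses, so the package ships a synthetic-micrograph generator with
exact ground truth; every stage is validated against geometry the
generator knows by construction.

## Calibration and conventions

All images are `calibrated_image` objects: a matrix of non-negative
intensities plus a physical pixel size in µm (confocal material in this
domain is typically acquired at 0.09 µm/px) and a marker label. Pixels
are isotropic; anisotropic TIFF calibration is rejected rather than
averaged. The physical centre of pixel `[i, j]` sits at
`((i - 0.5) s, (j - 0.5) s)`. Physical lengths convert to pixel counts by
round-half-up with a floor of one pixel, so the 1 µm membrane band is 11
px at 0.09 µm pixels. All neighbourhood operations use 8-connectivity,
matching the defaults of the FIJI-centred workflows this package
replaces. Multi-plane TIFFs are processed one 2D plane at a time; whether
to analyse single optical sections or projections is left to the user,
since either can be fed in as a plane.

TIFF resolution tags (`XResolution` in cm or inch units) are honoured on
read. The R TIFF writer used here does not expose resolution tags, so
`write_image()` stores the calibration in a JSON sidecar that
`read_image()` picks up transparently; an explicit override always wins.

## Segmentation

The HABP channel is segmented with an automatic threshold; the method
default is Otsu on a 256-bin histogram spanning the image's own intensity
range, which makes masks invariant under positive affine rescaling of
intensities. Percentile and fixed thresholds are provided for sensitivity
analysis, because the exact automatic-threshold variant used by any given
acquisition pipeline varies. Components smaller than `min_object_px = 4`
pixels are discarded as debris. Cells are segmented from the Thbs4
channel the same way, followed by hole filling (membrane-weighted
staining must still yield solid cell bodies), 8-connected labelling,
removal of regions below `min_area_um2 = 20` µm², and, by default,
removal of border-touching cells, whose truncated membranes would bias
per-cell compartment areas. Touching cells are not split — the synthetic
test scenes never place touching cells, and on real material this is an
acknowledged limitation of the approach.

## Skeleton metrics

Thinning is a parallel two-subiteration (Zhang–Suen) scheme. It preserves
the 8-connected component count (a degenerate blob that would vanish
keeps its most central pixel) but is, like all grid thinnings, slightly
anisotropic at fiber tips: a 3-px-thick bar of 201 px thins to a
centerline about 2 px shorter at each tip. Tolerances on recovered fiber
lengths (10%) absorb this.

The skeleton becomes a weighted graph: one node per pixel, one edge per
8-adjacent pair, weighted `s` for orthogonal and `sqrt(2) s` for diagonal
steps — the calibrated Euclidean step convention of skeleton-analysis
plugins. The longest shortest path of a component is the maximum pairwise
geodesic distance. For components with at least two endpoints the search
is restricted to endpoint pairs, which is exact on trees (verified
against a brute-force Floyd–Warshall oracle on random trees in the test
suite); pure loops fall back to the all-pairs maximum, whose value on a
cycle never exceeds half the cycle length. One consequence of the
diagonal-step convention worth knowing: at a right-angle corner the
geodesic cuts the corner through the diagonal edge, so an L of two 101-px
arms measures `198 s + sqrt(2) s` (17.95 µm at 0.09 µm/px), not 200
orthogonal steps. Components of fewer than 3 pixels are kept but flagged
`small`, so any filtering downstream is an explicit, recorded choice.

Per-component summaries report pixel count, endpoints (one neighbour),
junction pixels (three or more neighbours), and branches. Because
8-connected crossings produce small clusters of mutually adjacent
junction pixels, branch counting first merges such clusters, so a simple
plus-shaped crossing counts 4 branches.

Cable lengths pool into right-continuous ECDFs per condition. Whether to
pool per image or per animal is a study-level choice; the per-component
table is tagged with field, condition and region so either pooling can be
reproduced.

## Fractal dimension

Boxes of side ε tile the grid from a single fixed origin (partial boxes
at the far edges count), and the dimension is the ordinary least-squares
slope of `log N(ε)` against `log (1/ε)`. A single-origin tiling keeps
counts exactly reproducible and matches the simple tiling of the common
plugin implementations; multi-offset minimization is deliberately
omitted. The default size schedule is powers of 2 from 2 px to a quarter
of the short image side; masks whose short side is a power of 3 (the
analytic carpet patterns) use powers of 3 instead so the theoretical
counts are hit exactly. The fitted slope is clipped to the planar range
[0, 2] and flagged if clipping occurred. On the analytic suite the fit
recovers dimension 1 for a line, 2 for a filled square and
log 8 / log 3 ≈ 1.8928 for an order-5 Sierpinski carpet with R² ≥ 0.98.

## Compartments and the 1 µm membrane band

The membrane band is defined by Euclidean distance to the cell boundary:
a pixel is *membrane* when it lies within `band_width_um` of the boundary
(on both sides for the default symmetric band; `outer` and `inner`
variants are exposed). The band is realized with an exact Euclidean
distance transform rather than a square structuring element — a
chessboard band around a disk of radius r would cover ≈ 16 r w pixels
instead of the true annulus 4 π r w, a 27% overestimate, while the
distance-transform band stays within 5% of the annulus for r ≥ 50 px at
w = 11 px. Cell interior minus band is *intracellular*; everything else
is *extracellular*; the three codes partition the image exactly, so the
hyaluronan-area decomposition
`total = intracellular + membrane + extracellular` is an exact identity,
not an approximation. Where bands of adjacent cells would overlap, pixels
attribute to the nearest cell (ties to the lower label); the synthetic
scenes keep cells far enough apart that attribution is unambiguous.

Per cell, the package reports hyaluronan *area* in each compartment
(matching the area-based readout of the original analysis); an integrated
membrane-intensity column is available as an auxiliary output when the
raw image is supplied. Intracellular HABP spots are 8-connected
components of at least `min_spot_px = 3` pixels; a cell counts as
CD44-internalizing when at least `min_cd44_px = 5` CD44-positive pixels
lie in its intracellular compartment. Both floors suppress single-pixel
noise and are configurable.

## Lesion profiles

Core-to-penumbra profiles are radial: pixels bin by Euclidean distance of
their centres to a user-chosen core reference point (the figures this
reproduces show line profiles without a stated geometry; radial averaging
around the core generalizes a single line and is statistically steadier,
and a literal `line_profile()` mode is provided as well). Each channel
normalizes by its own maximum because the comparison is about profile
shape. Empty bins are reported as `NA`, never interpolated. The scar peak
is the bin centre of maximum normalized intensity, ties resolving to the
smallest radius. On synthetic ring lesions the recovered peak lands
within one bin of the scar-annulus midpoint, and the characteristic
ordering — Thbs4 confined to the scar border, GFAP spread over core and
scar — is reproduced.

## Group statistics

Cable-length distributions are compared with the Kruskal–Wallis rank test
(tie-corrected H, chi-squared reference with k−1 degrees of freedom),
computed via `stats::kruskal.test` and cross-checked in the tests against
an independent mid-rank implementation of

$$H = \frac{12}{N(N+1)} \sum_i n_i (\bar R_i - \bar R)^2 \Big/
      \left(1 - \frac{\sum_t (t^3 - t)}{N^3 - N}\right).$$

All-identical values return H = 0, p = 1 rather than an error. The
chi-squared approximation matches what standard statistics software
applies to these data; a permutation alternative was considered and left
out because the sample sizes here (hundreds of skeleton components) make
the approximation accurate. Type-I error is verified by simulation (1000
null replicates of 3 × 30 observations give a rejection rate within
[0.035, 0.065] at α = 0.05). Post-hoc pairwise testing after
Kruskal–Wallis is out of scope.

qPCR tables are semi-quantified as `fold = 2^{-ΔΔCt}` with
`ΔΔCt = (Ct_target − Ct_ref)_treated − (Ct_target − Ct_ref)_control`.

## The synthetic scenes — what they emulate, and what they do not

* `make_fiber_scene()` draws non-overlapping random polylines (0–2 bends
  by default) rasterized with anti-aliasing at 3 px thickness, emulating
  the cable-like interstitial matrix of ischemic areas. Arc length is
  computed on the polyline, not the raster, so truth lengths are exact.
  Default field: 1024 px at 0.09 µm/px (a ~92 µm confocal field); fiber
  lengths default to 9 µm with a configurable spread — population studies
  in the tests use a 1.5 µm standard deviation, a ~10–15% coefficient of
  variation typical of biological length distributions.
* `make_fractal_pattern()` produces the analytic line / filled square /
  Sierpinski-carpet masks with known dimension.
* `make_cell_scene()` places fully interior, non-overlapping cell disks
  (default radius 55 px ≈ 5 µm, an astrocyte-soma scale), an optional
  1-px hyaluronan ring on each perimeter, mutually disjoint intracellular
  and extracellular spots placed clear of the membrane band, and CD44
  puncta in exactly `round(fraction × n)` cells.
* `make_lesion_scene()` builds a core / scar-annulus / beyond geometry
  and assigns each marker channel to its zones.

Noise is additive Gaussian clipped at zero — enough to exercise the
automatic threshold. The scenes deliberately do **not** model a
point-spread function, Poisson shot noise, intensity gradients, touching
or overlapping cells, anisotropic voxels or 3D structure. Passing tests
therefore demonstrate that the measurement chain is correct on known
geometry at realistic scales; they do not certify segmentation quality on
degraded real material, where threshold choice and cell separation remain
the user's responsibility.

Generators are deterministic: identical arguments and seed give
bit-identical scenes, and the full pipeline writes byte-identical CSVs
for a fixed configuration and seed.

## Problem sizes and numerical choices in the shipped checks

The test-suite and the reproduction script run entirely on synthetic
scenes: 50 fibers of 9 µm in a 1024² field for length recovery; 100
components per condition (10 µm vs 20 µm means) for the power and
stochastic-ordering checks; 10 cells with 5 intracellular spots each for
compartment recovery; a 50 px disk with an 11 px band for the annulus
geometry; 100 random trees of up to 200 nodes against the brute-force
geodesic oracle; and 1000 null simulations for the Kruskal–Wallis
calibration. These sizes keep each stage's check at the scale the method
is used at while running in minutes on a single core.

## Known limitations

Watershed splitting of touching cells, 3D skeletons, lacunarity and
multifractal spectra, grayscale box counting, automatic lesion-core
detection, and registration across sections are out of scope. Zhang–Suen
thinning is anisotropic at tips and staircase segments, so pipeline-level
cable lengths for a rotated image can differ by a few steps even though
the geodesic diameter on a fixed skeleton is exactly invariant under
rotation and mirroring.
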