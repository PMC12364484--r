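# haquant

Quantification of hyaluronan matrix architecture in multichannel
fluorescence micrographs of the ischemic glial scar and the
subventricular zone (SVZ).

After focal brain ischemia, reactive astrocytes build a dense
hyaluronan-rich extracellular matrix around the lesion — the glial scar.
`haquant` is for imaging labs measuring how that matrix is remodelled:
it turns calibrated micrographs of the hyaluronan probe (HABP), the
newborn-astrocyte marker Thbs4, and the hyaluronan receptor CD44 into
per-field and per-cell readouts of matrix architecture, and provides the
nonparametric statistics used to compare them across conditions
(sham vs. days post-injury, cortex / striatum / corpus callosum / SVZ).

## What it computes

* **Matrix segmentation** — automatic (Otsu) thresholding of the HABP
  channel, debris removal, cell segmentation from the Thbs4 mask.
* **Cable lengths** — the segmented matrix is thinned to one-pixel
  skeletons; each connected skeleton becomes a weighted graph (step `s`
  orthogonal, `√2·s` diagonal, `s` = pixel size in µm) and is summarized
  by its **longest shortest path** (geodesic diameter)
  `max_{u,v} d(u, v)` — the hyaluronan cable length. Populations of
  cable lengths are pooled into ECDFs per condition.
* **Interconnectivity** — box-counting fractal dimension: the OLS slope
  of `log N(ε)` vs `log(1/ε)` for boxes of side ε tiling the mask.
* **Compartmental hyaluronan** — each field partitions exactly into
  intracellular / membrane (a 1 µm Euclidean band straddling each cell
  boundary; 11 px at 0.09 µm pixels) / extracellular; per cell: HA area
  per compartment, intracellular HABP spot counts, and a
  CD44-internalization flag.
* **Lesion profiles** — radial core-to-penumbra intensity profiles and
  scar-peak localization per marker.
* **Statistics** — Kruskal–Wallis (tie-corrected `H`, χ² reference) on
  grouped cable lengths, and `2^-ΔΔCt` semi-quantification for qPCR
  tables.
* **Synthetic scenes** — generators for fiber networks, analytic
  fractal patterns, cell scenes with membrane/punctate HA, and
  ring-shaped lesions, each with exact ground truth, so the entire
  pipeline is testable without real data.

## Worked example

Simulate a fiber field with known truth, quantify it, and compare two
conditions:

```r
library(haquant)

sc  <- make_fiber_scene(n_fibers = 25, length_um = 12, length_sd_um = 1.5,
                        image_size = 768, noise_sd = 8, seed = 42)
seg <- segment_matrix(sc$channels$HABP)
seg$report
#> # A tibble: 1 × 3
#>   method threshold foreground_fraction
#>   <chr>      <dbl>               <dbl>
#> 1 otsu        92.7              0.0160

sk <- summarize_skeletons(seg$mask)
head(sk, 4)
#> # A tibble: 4 × 7
#>   component n_pixels n_endpoints n_junctions n_branches lsp_um small
#>       <int>    <int>       <int>       <int>      <int>  <dbl> <lgl>
#> 1         1      130           2           0          1   13.3 FALSE
#> 2         2      133           2          60          3   11.7 FALSE
#> 3         3      137           2         124         10   10.9 FALSE
#> 4         4      110           2           0          1   10.7 FALSE
round(mean(sk$lsp_um), 2)
#> [1] 11.2          # generator truth: 12 µm fibers, tips shorten in thinning

fractal_dim(skeletonize(seg$mask))
#> <fractal_fit> dimension 0.9781 (R^2 0.9975, 7 box sizes)
```

The 25 skeletons average 11.2 µm against a 12 µm generator mean —
thinning trims a pixel or two per fiber tip — and a sparse network of
quasi-linear cables fits a dimension close to 1, as it should.

Per-cell compartmental quantification on a simulated astrocyte field:

```r
cells <- make_cell_scene(n_cells = 8, membrane_signal = TRUE,
                         n_intra_spots = 4, cd44_positive_fraction = 0.5,
                         seed = 42)
labs <- segment_cells(cells$channels$Thbs4)
comp <- compartmentalize(labs, band_width_um = 1)
rec  <- quantify_cells(labs, comp,
                       segment_matrix(cells$channels$HABP)$mask,
                       segment_matrix(cells$channels$CD44)$mask)
head(rec, 3)
#> # A tibble: 3 × 7
#>    cell cell_area_um2 ha_intracellular_um2 ha_membrane_um2 intracellular_spots
#>   <int>         <dbl>                <dbl>           <dbl>               <int>
#> 1     1          76.9                0.373            2.70                   4
#> 2     2          77.0                0.421            2.78                   4
#> 3     3          77.0                0.421            2.79                   4
internalization_fraction(rec)
#> [1] 0.5          # exactly the generator's CD44-positive fraction

glance(kruskal_wallis(list(sham = rnorm(50, 10), mcao = rnorm(50, 14))))
#> # A tibble: 1 × 5
#>   n_groups n_total statistic    df  p_value
#>      <int>   <int>     <dbl> <int>    <dbl>
#> 1        2     100      72.5     1 1.68e-17
```

Every spot count, membrane area and internalization flag above is checked
against the generator's ground truth in the test suite. A whole study
(many fields, conditions, regions) runs through `run_pipeline()` from a
YAML configuration, writing deterministic CSVs (`results.csv`,
`skeletons.csv`, `cells.csv`, `ecdf.csv`, `kw.csv`) plus a run log; a thin
command-line front end lives in `inst/cli/haquant.R`.

## See also

The methods vignette (`vignettes/haquant-methods.Rmd`) documents the
models, parameter defaults and units, numerical conventions, the design
decisions behind the band and skeleton definitions, what the synthetic
scenes do and do not emulate, and known limitations.
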