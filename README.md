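# punctakit

Quantification of fluorescent vesicle puncta in confocal images of single
cells, built for macroautophagy studies in large cells such as mouse
oocytes. Marker proteins — BECN1 (autophagy initiation), LC3B
(autophagosome membrane), LAMP1 (lysosome), EEA1 (early endosome) — form
discrete bright puncta; their number, size distribution, peripheral
localization and pairwise colocalization are the biological readouts.

The package implements the full measurement chain as composable,
pipe-friendly functions returning tibbles:

1. **Puncta pipeline** — z-stack maximum-intensity overlay, micron
   calibration (area = pixel count x `um_per_pixel`^2), 8-bit min-max
   conversion, white top-hat background suppression (image minus its
   opening with a flat disc), fixed-value thresholding (foreground =
   intensity >= T), and connected-component particle analysis (4- or
   8-connectivity) yielding a per-punctum table of areas, centroids and
   equivalent diameters `2 sqrt(A/pi)`.
2. **Size classes** — marker-specific partitions of `(0, Inf)` um^2:
   phagophore `(0, 0.196)`, autophagosome `[0.196, 1.767]` (i.e. 0.5-1.5 um
   diameter via `A = pi (d/2)^2`), lysosome `[0.03, 0.5]`,
   amphisome-candidate `> 10`, plus 1-um^2 and 0.1-um^2 ladder bins.
3. **Peripheral analysis** — automatic cell-mask estimation, the outermost
   10 um band by morphological erosion, and the fraction of large
   (> 10 um^2) puncta whose centroids fall in the band (`NA`, never 0,
   when there are no large puncta).
4. **Colocalization** — no-threshold Pearson correlation of two top-hat
   filtered channels over the cell mask, the whole frame, or the union of
   large puncta; percent reduction between group coefficients,
   `100 (r_ctrl - r_trt)/r_ctrl`.
5. **Group statistics** — normalization to a reference group's mean,
   mean +/- SEM, two-tailed unpaired Student's t-test, one-way ANOVA with
   Tukey HSD and compact letter display, dose-response summaries with
   viability-based exclusions; broom-style `tidy()`/`glance()` methods.
6. **Synthetic ground truth** — a generator that renders disc-shaped cells
   (default 75 um) with Gaussian-blurred hard-disc puncta of known areas in
   a 15-slice z-stack at 1 um spacing, including correlated two-channel
   pairs and peripherally biased cohorts, so every stage is testable
   without microscope data.

## Worked example

Simulate a noiseless cell, run the pipeline, profile the sizes, and
measure peripheral localization:

```r
library(punctakit)

acq <- acquisition_params(image_size_px = c(300, 300), noise_model = "none")
sim <- generate_cell(puncta_spec(n = c(10, 5, 1)), acq, seed = 7,
                     cell_diameter_um = 40, nucleus_diameter_um = 12)
tab <- run_pipeline(sim$stack, pipeline_params(threshold = 120))
head(tab, 4)
#> # A tibble: 4 × 5
#>   label area_um2 centroid_x_um centroid_y_um equivalent_diameter_um
#>   <int>    <dbl>         <dbl>         <dbl>                  <dbl>
#> 1     1   0.0675          4.75          27.4                  0.293
#> 2     2   0.337           6.38          23.4                  0.656
#> 3     3   0.045           6.22          29.2                  0.239
#> 4     4   0.045           9.15          34.6                  0.239
```

Sixteen puncta were planted and sixteen rows come back; each `area_um2` is
the punctum's projected area. Binning by the LC3B scheme:

```r
classify_puncta(tab, size_scheme("lc3b")) |> dplyr::filter(n > 0)
#>   class               lower_um2 upper_um2     n
#> 1 phagophore              0         0.196     7
#> 2 autophagosome           0.196     1.77      8
#> 3 amphisome_candidate    10       Inf         1
```

The planted mixture (small, autophagosome-sized, one large) is recovered.
The single large punctum sits in the outer 10 um of the cell:

```r
geom <- peripheral_band(estimate_cell_mask(overlay_stack(sim$stack)), 10)
peripheral_fraction(tab, geom)
#>   n_large n_in_band fraction band_width_um cell_radius_um
#> 1       1         1        1            10           20.0
```

Group comparison with reference normalization (one value per cell):

```r
df <- tibble::tibble(group = rep(c("young", "aged"), each = 5),
                     value = c(9, 11, 10, 12, 10, 6, 7, 5, 8, 7))
compare_two_groups(df, reference = "young")
#> <group_result> t_test: statistic = 5.27, p = 0.0007556
#>   young        n = 5   mean +/- SEM = 10.4 +/- 0.5099 (norm 1) **
#>   aged         n = 5   mean +/- SEM = 6.6 +/- 0.5099 (norm 0.635) **
```

The aged group carries 0.635x the reference mean and the difference is
significant (`**` = P <= 0.01). `simulate_cohort()` + `run_experiment()`
drive the same chain over a whole cohort on disk, writing per-cell CSVs,
size profiles, periphery and colocalization tables, a group report and a
hash manifest. A thin CLI over these functions ships in
`inst/cli/punctakit.R` (subcommands `simulate`, `analyze`, `periphery`,
`coloc`, `schemes`, `run-experiment`).

## Vignette

`vignettes/puncta-quantification.Rmd` documents the model and assumptions,
the bin-edge and band conventions, what the synthetic generator does and
does not emulate, and the package's numerical choices.
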