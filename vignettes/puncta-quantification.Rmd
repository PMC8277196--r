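---
title: "Quantifying vesicle puncta in single-cell confocal images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vesicle puncta in single-cell confocal images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
```

```{r setup, message = FALSE}
library(punctakit)
library(dplyr)
```

## The measurement problem

Macroautophagy activity in a cell is commonly read out by counting and
sizing the fluorescent puncta formed by marker proteins: BECN1 (autophagy
initiation), LC3B (autophagosome membrane), LAMP1 (lysosome membrane) and
EEA1 (early endosome). In large cells such as mouse oocytes (~75 um
diameter), each cell is imaged as a confocal z-stack — by default 15 slices
at 1 um spacing through the cell centre — and the puncta are quantified on a
2-D overlay of the stack. The biological questions are then about the
*size distribution* of the puncta (which vesicle class do they correspond
to?), their *spatial distribution* (do large puncta accumulate at the cell
periphery?), and the *colocalization* of two markers (is a large LC3B
punctum also EEA1-positive, i.e. an amphisome?).

punctakit implements this measurement chain end to end, together with a
synthetic-image generator that renders cells with fully known ground truth,
so that every stage can be validated without microscope data.

## The measurement chain

For one cell and one channel the pipeline is the composition

1. **calibrate** — attach the spatial scale (um per pixel). Every area is
   henceforth `pixel count x um_per_pixel^2`.
2. **overlay** — collapse the z-stack to a single image. We use a
   per-pixel maximum-intensity projection: puncta are sparse and bright, so
   the maximum preserves each punctum's peak regardless of its home slice.
   A sum projection is available behind a flag.
3. **8-bit conversion** — linear min-max rescale to integers in [0, 255]
   (half-up rounding; a constant image maps to 0). The rescale is
   per-image; because this changes what a fixed threshold means, the
   rescale range is recorded in the table's provenance.
4. **white top-hat** — the image minus its morphological opening with a
   flat disc (default radius 15 px). Structures that cannot contain the
   disc (puncta) survive; broader structures (diffuse cytoplasm, the cell
   body itself) are removed. The disc radius must exceed the radius of the
   largest punctum of interest: at the default 0.15 um/px scale, 15 px
   ~ 2.25 um, comfortably above the ~1.9 um radius of a 11-14 um^2
   amphisome-sized punctum.
5. **threshold** — foreground is `intensity >= T` (bright puncta, ImageJ
   "default dark" convention). `T` is a fixed 8-bit value chosen per
   replicate and *kept constant across experimental groups within that
   replicate*; an Otsu mode exists for exploration and is flagged in
   provenance.
6. **particle analysis** — connected components (8-connected by default,
   matching ImageJ Analyze Particles; 4-connected available) with per-
   component area, centroid and equivalent circular diameter
   `2 sqrt(area/pi)`. No minimum-area filter is applied by default because
   the size-class schemes bin even sub-0.196 um^2 puncta.

```{r pipeline}
acq <- acquisition_params(image_size_px = c(300, 300), noise_model = "none")
sim <- generate_cell(puncta_spec(n = c(10, 5, 1)), acq, seed = 7,
                     cell_diameter_um = 40, nucleus_diameter_um = 12)
tab <- run_pipeline(sim$stack, pipeline_params(threshold = 120))
nrow(tab)          # every planted punctum recovered
head(tab, 3)
```

## Vesicle size classes

Measured areas are binned into named, marker-specific classes:

* **LC3B / BECN1**: phagophore `(0, 0.196)` um^2, autophagosome
  `[0.196, 1.767]` um^2 (the documented 0.5-1.5 um diameter converted by
  `pi (d/2)^2`), a 1-um^2 ladder, and an amphisome-candidate class
  `> 10` um^2.
* **LAMP1**: lysosome `[0.03, 0.5]` um^2, a 0.1-um^2 ladder up to
  `> 1` um^2.

Bin edges are a convention the source material leaves open; we fix it once:
dash-quoted ranges ("0.196-1.767") include both printed bounds, ">x"
classes are strictly open below, and ladder bins are half-open
`(lower, upper]`. With these rules each scheme is an exact partition of
`(0, Inf)` — every punctum falls in exactly one class, and class counts sum
to the total. (A left-closed/right-open ladder convention would leave the
single value 10.0 um^2 unclaimed between a `[9, 10)` bin and a `> 10`
class, which is why the half-open-left form was chosen.) Overlapping named
ranges (the lysosome range overlaps the phagophore range) never co-reside
in one scheme; schemes are per marker.

```{r classes}
round(diameter_to_area(c(0.5, 1.5)), 3)
classify_puncta(tab, size_scheme("lc3b")) |> filter(n > 0)
```

## Peripheral localization

Large puncta (> 10 um^2) accumulate at the periphery of aged cells. The
cell mask is estimated from the analysed channel itself (the diffuse
cytoplasmic signal): Otsu threshold of a Gaussian-smoothed copy (sigma
2 um), largest connected component, holes filled. Bright puncta are clipped
to the 90th intensity percentile before Otsu so the threshold separates
background from cell body rather than puncta from everything else. A
user-supplied mask or a fitted circle (`circular_cell_geometry()`)
overrides the estimate.

The peripheral band — the outermost 10 um of the cell — is the mask minus
its erosion by a disc of that radius (rounded to pixels). How the original
Fiji analysis delineated the band is not recoverable; erosion is a
reproducible stand-in and agrees with a distance-transform definition on
circular masks. Band membership of a punctum is decided by its **centroid**
(a punctum larger than 10 um^2 can straddle the band edge; the centroid
rule is unambiguous), with an any-pixel mode behind a flag. With no large
puncta the fraction is reported as missing, never as 0.

For a circular cell of radius R with band width w, uniformly placed
centroids fall in the band with probability `1 - ((R - w)/R)^2`; for
R = 37.5 um and w = 10 um that is ~0.462, which the band machinery
reproduces within binomial sampling error (tested at n = 2000).

## Colocalization

Two-channel colocalization is quantified as the Pearson correlation of
pixel intensities with **no intensity threshold**, after white top-hat
filtering of each channel (radii recorded per channel). The ROI defaults to
the estimated cell mask — background pixels outside the cell share low
intensity in both channels and would inflate the correlation — with a
whole-frame mode for parity with common Coloc-2 usage; both are recorded in
the result. `coloc_in_large_puncta()` restricts the ROI to the union of
puncta above 10 um^2 from a reference-channel table, the readout used to
identify amphisomes. A correlation over a constant channel is reported as
missing. `percent_reduction(r_control, r_treated)` expresses treatment
effects as a signed percentage of the control coefficient.

Manders coefficients, Costes randomization and thresholded Pearson variants
are deliberately out of scope.

## Group statistics

Per-cell values are the statistical unit (5-15 cells per group is typical).
Conventions:

* values are presented normalized to the reference (young / untreated)
  group mean, whose normalized mean is exactly 1;
* summaries are mean +/- SEM (`sd/sqrt(n)`);
* two groups: two-tailed unpaired Student's t-test, equal variances by
  default ("Student's" taken literally; Welch behind a flag);
* three or more groups: one-way ANOVA followed by Tukey HSD (the standard
  companion to one-way ANOVA; Bonferroni optional), with compact letter
  display — groups sharing no letter differ at alpha = 0.05. Two groups
  are accepted too, where ANOVA reproduces the t-test (`F = t^2`).
* significance markers: `*` for P < 0.05, `**` for P <= 0.01.
* dose-response summaries flag dose levels whose viability falls below 50%
  as excluded from statistics, with the reason recorded, rather than
  silently dropping them.

```{r stats}
df <- tibble::tibble(group = rep(c("young", "aged"), each = 5),
                     value = c(9, 11, 10, 12, 10, 6, 7, 5, 8, 7))
res <- compare_two_groups(df, reference = "young")
tidy(res)
glance(res)
```

## The synthetic generator

`generate_cell()` renders what the pipeline expects to see: a disc-shaped
cell body (default 75 um diameter, matching a mouse oocyte; the source
work does not report cell diameter or pixel size, so these defaults are
conventions) at a low uniform intensity above background, a nucleus, and
bright cytoplasmic puncta, as a 15-slice z-stack at 1 um spacing on a
640 x 640 px grid at 0.15 um/px.

Design choices that matter for validation:

* **Puncta are hard discs, Gaussian-blurred**, not pure Gaussian spots, so
  the area ground truth is well defined — the pipeline measures area, so
  fixtures must be area-true. Ground truth records both the analytic area
  `pi r^2` and the *rendered* pixel area (hard-disc pixel count times
  um^2/px). The two differ by discretization: a 4-px punctum can deviate
  from `pi r^2` by ~25% from pixelation alone, and the discrepancy shrinks
  as the pixel size decreases. Recovery tests therefore compare measured
  areas against the rendered object; the rendered-vs-analytic gap is
  checked separately as a discretization property.
* **Each punctum lives on a home slice** and attenuates in neighbouring
  slices by a Gaussian axial profile (sigma 0.75 um), so the projection
  stage is exercised nontrivially.
* **The lateral PSF sigma defaults to 0.05 um**, tighter than a
  diffraction-limited 60x/1.35 objective (~0.09 um), again favouring
  area-truth over optical realism; it is configurable.
* **Peak intensity is constant by default** (200 a.u. over a background of
  5 and a cell body of +10), so one fixed threshold means the same thing
  for every punctum. Validation runs threshold at half the post-top-hat
  amplitude (~120 of 255, an FWHM criterion): for a blurred step edge the
  half-amplitude contour sits at the true disc boundary, which is the
  principled analogue of choosing "the threshold that best represents the
  original detail" on real images. The package default threshold remains
  20, a value representative of real usage on dimmer data.
* **Noise** defaults to Poisson shot noise plus Gaussian read noise
  (sd 2 a.u.); `"none"` yields bit-reproducible noiseless fixtures.
  Identical (spec, seed) pairs give bit-identical stacks and truth.
* `generate_correlated_pair()` places a controlled fraction of puncta at
  identical coordinates in both channels; `generate_peripheral_cohort()`
  places large puncta in the outer band with a controlled probability;
  `simulate_cohort()` writes a whole young-vs-aged experiment to disk
  (fewer lysosome-range and autophagosome-range puncta, more and more
  peripheral large puncta in the aged group).

What the generator does **not** emulate: realistic PSF shape, spectral
bleed-through, intensity heterogeneity within and across puncta,
non-circular cells, touching cells, autofluorescence gradients. Passing
the planted-truth suites therefore demonstrates the correctness of the
measurement chain, not robustness to every pathology of real micrographs;
threshold choice on real data remains the operator's responsibility.

## Numerical choices and degenerate inputs

* Morphology (opening, erosion) runs in EBImage with a shared disc
  structuring element; out-of-image neighbours are ignored (neighbourhood
  intersected with the image domain). The white top-hat is checked against
  a brute-force erosion/dilation oracle.
* Connected-component labeling is implemented in-package (both 4- and
  8-connectivity) and checked exhaustively against a recursive flood fill
  on all 65,536 4 x 4 binary grids, and against EBImage's `bwlabel`
  (which is 4-connected) on random grids.
* Centroids use the pixel-centre convention: the centre of pixel `[1, 1]`
  is `(0, 0)` um. Band membership maps a centroid to its nearest pixel.
* Sub-pixel puncta (possible at 0.03 um^2, below one pixel at the default
  scale) always light at least their nearest pixel, so planted and
  rendered counts agree.
* Empty cases are explicit: empty masks give empty tables; an all-zero
  image is a valid (constant) 8-bit image; a blank field errors at cell-
  mask estimation; zero large puncta give a missing peripheral fraction;
  constant channels give a missing correlation.
* Ties at bin edges are governed by the scheme conventions above; ties in
  the t-test (identical groups) return statistic 0 and p = 1.

## Problem sizes used in validation

The shipped test-suite and the acceptance script validate on
300 x 300 px fixtures holding a 40-um cell (same calibration and stack
geometry as the full-size default) for per-stage checks, a 12-cell
young-vs-aged cohort at the full 640 x 640 px default for the end-to-end
run, 2,000 placements for the annulus law, and 10,000 replicates for the
null-calibration of the t-test. These sizes were chosen as the smallest
that leave the statistical assertions well-powered.

## Known limitations

* One cell per field is assumed; multi-cell fields error rather than being
  segmented.
* The analysis is strictly 2-D after projection; overlapping puncta in z
  merge, and no voxel-level segmentation is attempted.
* Puncta that touch within the projection merge into one particle — a
  limitation shared with the original ImageJ workflow.
* The TIFF writer used here does not expose resolution tags, so
  calibration travels in a JSON sidecar (or the config) instead.
* Fixed thresholds interact with the per-image 8-bit rescale; comparing
  groups assumes comparable acquisition settings within a replicate, which
  the provenance records but cannot enforce.
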