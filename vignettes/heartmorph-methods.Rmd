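---
title: "Quantifying cardiomyocyte morphology and capillary supply with heartmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiomyocyte morphology and capillary supply with heartmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartmorph)
```

## The measurement problem

Pathological cardiomyocyte hypertrophy and microvascular rarefaction are
central readouts in cardiac research, yet both are tedious to quantify on
histology: a single field contains hundreds of myocyte profiles, and manual
outlining is slow and observer-dependent. heartmorph implements a
semiautomated pipeline for two complementary stainings:

* **Brightfield, Gomori silver.** Reticular fibres outline the myocytes as
  a pale network, the muscle cytoplasm is reddish, capillary lumens are
  unstained. Segmentation, colour/size/position classification and
  morphometry run from a single RGB image.
* **Immunofluorescence, WGA-based.** A wheat germ agglutinin membrane
  channel drives segmentation; DAPI supplies nuclei, CD31 supplies the
  capillary endothelium, or an intracellular marker (e.g. pro-ANP)
  supplies a per-cell expression signal.

The analysis unit is a field image exported from a whole-slide scan (not
the slide itself), with an explicit user-supplied calibration in
micrometres per pixel — exported regions carry no trustworthy physical
metadata, so the package never infers calibration from files.

## Segmentation model

Brightfield images are converted to luminance (Rec. 601 weights, as in
common image-analysis software) and a 3×3 morphological gradient
(dilation − erosion) turns the pale boundary network into a ridge system.
The membrane channel of a fluorescence image is a ridge image already and
is used directly.

Instance segmentation is a **marker-controlled watershed with an h-minima
dynamic** as its single tunable: regional minima whose depth below their
lowest saddle exceeds the user-chosen *tolerance* survive as markers
(computed via morphological reconstruction by erosion of `relief + h` over
`relief`), shallower minima are merged. A Meyer flood then grows one
4-connected basin per marker; pixels reached by two basins become
watershed-line pixels (label 0), and ties on plateaus are resolved in FIFO
order so the result is deterministic. Labels are renumbered 1..n in raster
order of each basin's first pixel, which makes instance ids reproducible
across runs and platforms.

The tolerance has no sensible universal default — it depends on staining
contrast — so the batch entry points require it explicitly, and
`suggest_tolerance()` reports the region count over a sweep to support the
choice. Manual correction of missing boundaries is supported by
`merge_manual_lines()`: painted line pixels are raised above the global
relief maximum (plus the tolerance) and the watershed is re-run, so a
complete cut always splits its region. An optional Gaussian pre-blur
before the gradient (`blur_sigma`, default off) is provided for noisy
acquisitions; it is a convenience, not part of the core contract.

## Classification rules

All thresholds live in one `analysis_config()` object:

| parameter | default | meaning |
|---|---|---|
| `hsb_range` | 240–360°, 32–100%, 54–100% | colour window of stained muscle (hue, saturation, brightness) |
| `cm_min_area_um2` | mouse 60, human 50 | minimum cardiomyocyte cross-sectional area, µm² |
| `nucleus_area_um2` | 6–100 | nucleus area window, µm² |
| `capillary_area_um2` | 1.5–100 | capillary area window, µm² |
| `contact_max_distance_um` | 2 | maximum capillary–myocyte edge distance for a contact, µm |
| `exclude_border_cm` | `TRUE` | drop partially captured cells at the image border |

Brightfield instances are classified by a rule cascade
(`classify_gomori()`): a **cardiomyocyte** matches the colour window and
the species area floor and does not touch the border; a **cardiomyocyte
nucleus** lies (≥ 50% of its pixels) inside the hole-filled footprint of a
single cardiomyocyte with area in the nucleus window; a **capillary** is
an *unstained* instance outside all cardiomyocytes with area in the
capillary window; everything else is removed with the failing rule
recorded. All area comparisons are inclusive. Three summary choices
deserve comment:

* An instance's colour is summarised by per-channel **medians** over its
  pixels, which are robust against the dark nucleus pixels inside a
  myocyte profile. Whether the original macro required all pixels, a
  fraction, or an average inside the window is not specified anywhere;
  medians are our documented choice.
* The hue window **does not wrap**: a pure red hue of 0° fails the
  240–360° window even though such tissue looks "reddish". Users whose
  staining drifts towards hue 0 should widen the window deliberately
  rather than rely on wrap-around.
* Capillary candidacy requires *failing* the colour match. Capillary
  lumens carry no stain, and without this condition any small stained
  fragment between cells (for example a partially captured myocyte
  profile below the area floor) would be counted as a capillary, which
  contradicts the floor's purpose.
* "Within" and "outside" are made exact at pixel level: containment uses
  ≥ 50% of the candidate's pixels inside one filled footprint, and
  "outside" means zero overlap between the candidate's 1-px dilation and
  any filled footprint, so shared watershed-line borders do not create
  spurious overlap.

Fluorescence classification (`classify_fluo()`) has no colour channel for
the myocytes, so cardiomyocytes are classified **by size only** (no upper
bound is applied). Nuclei and capillaries come from Otsu (default) or
IsoData global thresholds of the DAPI and CD31 channels; nucleus
components must lie in cardiomyocytes, capillary components are extracted
*after zeroing every cardiomyocyte footprint pixel*, so capillary masks
and cell footprints are disjoint by construction. The Gomori size windows
are reused for fluorescence nuclei and capillaries; the source protocol
carries its later steps over from the brightfield macro without restating
the limits, and we document that reuse as an assumption.

## Morphometry

Every retained instance is measured in calibrated units
(`measure_instances()`): area (pixel count × mpp²), centroid, border
contact, and Feret diameters. Pixels are modelled as **unit squares** and
the convex hull of all pixel corners is measured by rotating calipers:
the maximum Feret diameter is the largest hull-vertex distance, the
minimum Feret diameter (MinFeret) the smallest width over directions
perpendicular to hull edges. The unit-square model avoids degenerate
zero-width instances (a single pixel has MinFeret 1 px) and matches the
behaviour of common image-analysis Feret implementations.

MinFeret is the preferred size measure for sectioned myocytes: cells are
elongated and the sectioning plane is never exactly perpendicular, so the
measured *area* of an oblique section grows like 1/cos(tilt) while the
width between parallel supporting lines barely changes. The acceptance
suite demonstrates this directly: a 16 × 40 µm profile rasterised at 19
orientations keeps MinFeret within 5% of 16 µm, while oblique "cuts" of
the same prism vary in area by more than 40%.

## Relations

Capillary contacts per cardiomyocyte follow the 2 µm rule: a capillary
contacts a cell when the minimum Euclidean distance between their pixel
centres is at most `contact_max_distance_um`. One capillary may contact
several cells and counts for each. The per-cell density `cc_per_area`
(contacts ÷ cell area) is computed per cell and then averaged — this
per-cell-then-average convention matches per-animal aggregation and is
what makes the measure robust to myocyte size differences between groups.
Per-cell expression (`expression_per_cm()`) is the percentage of a
cardiomyocyte's pixels covered by the thresholded marker mask.

## The synthetic-tissue generator

No reference image data exist for this pipeline, so validation rests on a
seedable generator (`tissue_spec()` / `generate_tissue()`) that produces
both renders *and exact analytic ground truth*:

* Cells are a Lloyd-relaxed Voronoi tessellation computed exactly by
  half-plane intersection. Each interior cell is scaled towards a sampled
  MinFeret target and then eroded by half the boundary gap; erosion of a
  convex polygon by a disk reduces its MinFeret by exactly the gap width,
  so the true MinFeret equals the target whenever the tessellation leaves
  room. Targets are rank-matched to the available space (largest target
  to the roomiest slot), which removes the truncation bias random
  assignment would put on the realised mean. Border cells stay unscaled
  and touch the field edge, exercising the border-exclusion rule.
* Capillaries are disks at cell junctions; neighbouring cells are
  chord-clipped so every disk–cell gap is either ≈ 1.2–1.5 µm (an
  unambiguous contact under the 2 µm rule) or ≥ 2.7 µm (an unambiguous
  non-contact). The exact contact graph is part of the ground truth.
* Nuclei are ellipses fitted inside eligible cells (polygon area
  ≥ 140 µm², so a cell stays above the area floor after its nucleus is
  carved out of the watershed basin).
* Ground-truth area and Feret values come from the final polygon/ellipse
  geometry, giving an oracle independent of rasterisation.

Defaults describe healthy mouse myocardium at a 40× scan: 0.25 µm/px,
mean cell MinFeret 14 µm (SD 2 µm, truncated at ±2.5 SD and never below
11 µm so that every interior myocyte stays unambiguously above the 60 µm²
floor after rasterisation losses), capillary density 0.85 per junction
(≈ 3 contacts per cell), nucleus fraction 0.32, noise SD 2 grey levels.
The hypertrophic scenario raises the mean MinFeret to 16 µm. Capillary
radii (1.0–1.8 µm) and nucleus axes are drawn well inside the size
windows so that classification on noise-free renders is exact by
construction; `include_edge_cases = TRUE` injects deliberate
boundary-case structures (a below-floor cell, pale/dim/unstained cells,
an oversized and an undersized nucleus, an undersized capillary) to
exercise each filter on both sides.

What the fixtures do **not** emulate: staining variability and uneven
illumination, fibrosis and inflammation, autofluorescence, out-of-focus
blur, and non-convex myocyte profiles. Passing the suite therefore
demonstrates the correctness of the algorithms and rules, not robustness
to degraded real-world staining — on real slides the manual tolerance
choice and the correction loop carry that burden.

### Numerical behaviour and known limitations

* Watershed-line pixels carry label 0 and belong to no instance, so a
  measured basin differs from the rendered cell by up to about one pixel
  per side. On the default fixtures the pipeline's MinFeret agrees with
  the analytic truth within one pixel-equivalent for ≈ 94% of cells and
  within two for all of them; group means are recovered to a few tenths
  of a percent. Measured areas are systematically a few percent below
  polygon areas (line pixels and carved nuclei), one reason MinFeret is
  the recommended size measure.
* In fluorescence mode a basin is the cell's *influence zone* — the cell
  plus its share of the bright membrane band. Expression fixtures
  therefore use densely packed cells (`dense_packing = TRUE`) whose
  basins coincide with their rendered footprints; with that geometry the
  designated per-cell positive fractions {0, 25, 50, 100}% are recovered
  within 2 percentage points.
* The realised group means sit slightly below the requested 14/16 µm
  (≈ 1–3%, from junction clips and finite fields); recovery is always
  judged against the generator's realised truth, which is exact.
* The descent-oracle comparison for the watershed excludes pixels whose
  steepest-descent path crosses a watershed-line pixel (where a
  line-forming and a partitioning convention legitimately differ); on
  smooth multi-well reliefs that leaves > 80% of pixels, on which
  agreement is exact.

## Problem sizes used in the validation suite

Test fixtures use fields of 80 × 60 to 200 × 150 µm at 0.25 µm/px
(≈ 30–90 cells per field); the two-group recovery experiment uses nine
150 × 110 µm images per group. These sizes give stable group statistics
while keeping the full suite fast; all thresholds and generator settings
are identical to what an analysis of full 433 × 270 µm fields would use.

## Worked example

```{r example, eval = FALSE}
library(heartmorph)

spec <- tissue_spec(seed = 7, noise_sd = 0)
tis  <- generate_tissue(spec)
img  <- render_brightfield(tis)

cfg <- analysis_config("mouse", watershed_tolerance = 10)
an  <- analyze_gomori(img, cfg, image_id = "demo")
an$report$class_summaries

# manual correction loop: write the report + overlay, inspect, exclude
write_report(an$report, "demo")
ov <- render_overlay(img, an$labels, an$report$records,
                     legend_path = "demo_legend.csv")
write_rgb_png(ov, "demo_overlay.png")
# ... after writing ids to exclude into demo_exclusions.txt:
# run_correct("demo", "demo_exclusions.txt")
```
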