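---
title: "Quantifying planar polarity and biomechanics of neuropore closure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying planar polarity and biomechanics of neuropore closure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnpolarity)
```

## The measurement problem

Closure of the posterior neuropore (PNP) — the last open stretch of the
mouse neural tube — depends on planar-polarised cell behaviour. Three image
measurements capture it:

1. **Orientation statistics** of surface-ectoderm cell long axes and cell
   divisions along the mediolateral (ML) / rostrocaudal (RC) axes.
2. **Junctional F-actin enrichment** on ML- versus RC-oriented cell borders
   of the neuroepithelial apical surface, including the supracellular
   "ladder" profiles that span neighbouring cells.
3. **Tissue-scale morphometry and mechanics**: PNP length/width, signed
   neural-fold elevation (eversion when negative), the basal:apical
   neuroepithelial length ratio, and the recoil widening after laser
   ablation of the zippering point.

All of these start from 3D confocal stacks in which the structure of
interest — the outermost cell layer — overlies brighter and dimmer deeper
tissue. The package therefore reconstructs the "surface subtraction"
preprocessing step and validates every stage on synthetic images with exact
ground truth, since no public reference acquisitions exist for this assay.

## Angle convention

Symmetry around the dorsoventral axis is assumed whenever angles are
computed: `fold_angle()` maps any angle to [0°, 90°], 0° = ML and 90° = RC,
and folding is idempotent. One subtlety matters for statistics: folding
reflects the axial circle at 90°, so the circular mean of *folded* values is
biased inward for distributions centred on 0° or 90° (a sample at 95° folds
to 85°, making the folded sample one-sided). `measure_cells()` therefore
also reports the unfolded axial orientation in [0°, 180°)
(`orientation_axial_deg`), and `axial_mean_deg()` / `axial_dispersion()`
operate on doubled angles, which handles the wraparound correctly. Folded
values are the right representation for the [0°, 90°] histograms and
chi-square tests; axial values are the right one for circular means.

## Surface subtraction

The reconstruction is the literal sequence: reslice to a canonical
(ML, RC, DV) order → binarise → per-column top-surface scan → band mask →
subtract → maximum projection.

- **Binarisation** defaults to a single global Otsu threshold over a 256-bin
  histogram of the whole stack (`binarise`); a fixed threshold is available.
  A constant stack raises a degenerate-histogram error rather than silently
  returning an empty mask.
- **Depth-map smoothing**: the raw first-foreground-voxel depth map is
  median-filtered (radius 2 lateral positions, NA-aware) before band
  construction. Isolated noise spikes above the surface would otherwise
  anchor pinhole artefacts; the filter trades this against a small lag on
  steep surfaces.
- **Band convention**: the band starts at the detected surface voxel
  (inclusive) and extends ventrally `band_depth_um` (default 5 µm),
  converted to slices by rounding half-up — 5 slices at a 1 µm z-step.
  "About 5 µm" is approximate in practice; a fixed convention makes the
  measurement reproducible.
- Peeling multiplies by the band mask, so it is exactly idempotent and never
  increases total intensity.

## Border polarity

`build_border_graph()` defines a border as the set of pixels whose
8-connected neighbourhood contains exactly two cell labels; points where
three or more cells meet are tricellular vertices. `measure_borders()`
takes each border's orientation from the principal axis of its pixel set and
classifies it ML below 45° and RC at or above (the 45° boundary is the
symmetric choice for a binary dichotomy; the tie goes to RC for
determinism). Intensity is averaged over the border pixels dilated by one
pixel — capturing the junctional signal despite 1-px segmentation offsets —
*excluding* pixels claimed by more than one border's dilation zone and
pixels around tricellular vertices. Vertex exclusion is standard in
junctional polarity quantification: vertex signal mixes differently
oriented borders, and on phantoms it otherwise biases recovered ML:RC
ratios downward by roughly 15%.

Per-cell ratios are length-weighted by default (unweighted means overweight
short borders; an unweighted mode exists). Cells lacking either class are
excluded with a log entry rather than producing infinite ratios, and cells
touching the image edge are excluded because their borders are truncated.
The embryo score is the median per-cell ratio, flagged invalid below 35
cells.

**Profiles.** Enrichment is thresholded at `k` × median border intensity
(the original identification was visual, so the threshold is explicit and
must be reported with any result; the pipeline default is k = 1.5, and the
cohort analysis uses k = 1.25, chosen for a programmed anisotropy of 1.5
where ML borders sit ~50% above the median). Chains grow greedily from the
brightest unused enriched border, taking at each vertex the continuation
with the smallest orientation change — a deterministic mimic of visually
tracing ladder-like profiles. A single enriched border already spans two
cells and counts as a minimal profile.

Two properties pin the scale conventions: the score is invariant to
multiplying the image by any positive constant, and swapping the ML/RC axis
roles reciprocates every ratio (checked to within discretisation on
noise-free phantoms).

## Tissue morphometry

Landmarks are supplied as annotation tables (digitisation is manual in this
assay); an optional CLAHE helper (`clahe_enhance`, rolling-ball background
subtraction approximated by grayscale opening, then CLAHE, with the
two-step default schedule of blocks 50/30, bins 150/100, slope 3, radius
30 px) supports visual landmarking only and never feeds intensity
quantification. Elevation is the mean dorsoventral offset of the two fold
tips from the ventral apical midline point — negative values mean eversion.
The basal:apical ratio is a ratio of polyline arc lengths, hence scale
invariant. Ablation widening is measured in both frames at the
*pre-ablation* zippering-point level, because the ablation destroys the
landmark itself.

## Statistics

Wrappers over the standard machinery, with the conventions fixed:

- `chi_square_vs_random()`: Pearson chi-square of binned folded angles
  against expectations proportional to bin widths (uniform on [0°, 90°]),
  df = bins − 1. Default bins are 15° wide — six bins balance resolution
  against expected-count validity, and the width is configurable. Expected
  counts below 5 warn by default; `merge_bins = TRUE` merges adjacent bins
  left-to-right until each group's expectation reaches 5.
- `two_sample_t()` "accounts for homogeneity of variance" literally: an
  F-test on the variances at α = 0.05 gates a pooled versus Welch test;
  both can be forced.
- `anova_oneway()` adds Bonferroni-adjusted pooled-SD pairwise tests and
  guards the zero-within-variance degeneracies explicitly.
- `regression_slope_tests()` compares slopes via the nested F-test of a
  common-slope (separate intercepts) model against separate slopes:
  F = (RSS_common − RSS_separate) / (RSS_separate / (n_a + n_b − 4)).
  Perfectly collinear input is flagged degenerate instead of reporting an
  unstable F.
- Group elevation comparisons across fractional PNP positions are
  per-position two-sample tests with Bonferroni correction across the three
  positions; repeated-measures mixed modelling is deliberately out of scope
  (off-the-shelf machinery, not this package's contribution).
- All tests are two-tailed; every result can be serialised as a one-row
  audit record (`stat_summary_row`).

## The phantoms: what they emulate, and what they do not

`generate_sheet_stack()` renders a curved epithelial sheet: a sinusoidal
surface height field (default amplitude 10 µm, wavelength 60 µm — gentle
undulation relative to a ~7 µm cell, as in the relatively flat dorsal
midline region this assay analyses), carrying a tessellation of ~90 cells
over a 57 µm field at 0.59/0.59/1 µm voxel spacing, a 5 µm-thick cell
layer, a dimmer second layer 15 µm below, and additive Gaussian noise
clipped at zero (default SD 10 against border intensity 150, i.e. ~7%).

Design choices worth recording:

- **Tessellation seeding.** Seeds sit on a jittered hexagonal lattice
  (jitter 0.08 of the pitch) followed by one isotropic Lloyd relaxation,
  and cells are assigned by a per-cell anisotropic metric compressed along
  the cell's programmed long axis (factor `elongation`, default 1.4; the
  rendered aspect ratio grows with its square). Uniform-random seeding was
  tried first and rejected: its polygons carry large intrinsic shape
  anisotropy, so the rendered long axis cannot track the programmed one
  (7–10° mean error even after many Lloyd steps), which would make
  orientation ground truth meaningless. The hexagonal lattice keeps
  epithelium-like packing statistics while making programmed orientations
  realisable.
- **Border painting.** Border intensities are painted over exactly the same
  1-px-dilated pixel zones the measurement reads, ML borders at
  `a` × the RC intensity, optionally with per-border lognormal variability
  (`border_cv`) emulating biological heterogeneity. With zero noise the
  programmed anisotropy is recovered exactly; maximum projection over the
  noisy band adds a small symmetric bias (the max of ~5 noise draws), which
  keeps recovery within ~6% at 10% noise.
- **Orientation ground truth.** Per-cell programmed angles are drawn from a
  von Mises distribution on doubled angles (Best–Fisher sampler; κ = 0 is
  uniform). At moderate concentration (κ = 16) neighbouring cells with
  different programmed axes compete for territory, so the *realised* long
  axis deviates from the programmed one by ~3° on average — a property of
  the tessellation, not of the measurement. Per-cell recovery is therefore
  assessed on a strongly polarised sheet (κ = 32, error ≈ 2.5°), while
  population-level properties (circular mean within 5°, dispersion strictly
  decreasing in κ) are assessed at κ ≤ 16.
- The phantoms deliberately omit optical point-spread, photobleaching,
  multi-channel crosstalk and realistic zippering-point geometry. Passing
  tests therefore demonstrate that the measurement chain is unbiased and
  correctly calibrated on images with the assumed structure — not that it
  is robust to every optical artefact of a real acquisition.

`phantom_surface_image()` renders only the lateral surface image (what the
projection of the 3D phantom yields) and shares the lateral generator and
ground-truth semantics; it is used where many embryos are simulated and the
peeling step itself is not under study. The 3D peel → project path is
validated separately across amplitudes and noise.

## Null calibration at the embryo level

Cells within an embryo share borders, so their ratios are positively
correlated and a within-embryo t-test across cells would be
anti-conservative by construction. The embryo is the unit of analysis: the
null simulation scores 200 independent isotropic (a = 1) phantom embryos,
then tests 9-embryo cohorts against a score of 1; the rejection rate at
α = 0.05 calibrates to ~5% (4.1% in `analysis/04_polarity.R`). The same
embryo-level design powers the two-group comparison: with 9 embryos per
group and a 0.3 score difference at SD 0.15, the two-sample test rejects at
α = 0.01 in well over 80% of replicates.

## Problem sizes

The standard phantom is a 96 × 96 × 40–56 voxel stack (~57 µm field) with
~90 cells; validation sweeps use 3–18 such phantoms per check, 200
two-dimensional embryos for null calibration, and 2000 replicates for
Monte-Carlo calibration of the tests. These sizes were chosen so each
validation isolates one property at full precision of its assertion; all
figures reported in the README and by `scripts/acceptance.R` are computed
at run time at exactly these sizes.

## Known limitations

- The surface scan keeps only the first surface per column: strongly folded
  surfaces that overhang (two tissue crossings per column) are out of
  scope, as is mesh-based tissue cartography.
- Segmentation is an input; the watershed-free border graph assumes
  integer-labelled, gap-free label maps.
- The enrichment-profile delineation (threshold k and greedy chaining) is a
  reconstruction of a procedure originally done by eye; results should
  always be reported together with k.
- Division events are annotated centroid pairs; anaphase/telophase
  identification is manual by design.
- `clahe_enhance` approximates rolling-ball background subtraction by
  grayscale opening; it is a visual aid only.
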