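---
title: "Quantifying placental villous and capillary morphology from H&E micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying placental villous and capillary morphology from H&E micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(villimorph)
```

## The problem

Preeclampsia (PE) is a hypertensive disorder of pregnancy rooted in abnormal
placental development. Light microscopy of hematoxylin-and-eosin (H&E)
stained placental sections shows the chorionic villi — the branching tissue
units where maternofetal exchange happens — and the fetal capillaries inside
them. `villimorph` implements a quantitative pipeline over such micrographs:
segment villi and capillaries, extract ten morphometric features per
subject, and ask which features separate PE from normotensive placentae.

The pipeline has four stages, each usable on its own:

1. **Preprocessing** — grayscale conversion, median denoising, global
   histogram equalization.
2. **Segmentation** — Otsu thresholding for villi, morphology plus stain
   color deconvolution and CIELAB thresholding for capillaries.
3. **Morphometry** — counts, areas, perimeters, equivalent diameters, and
   two capillarization indices.
4. **Statistics** — two-sample t-tests, Fisher's linear discriminant
   analysis (FLDA) with leave-one-out (LOO) accuracy ranking, hierarchical
   clustering, and PCA.

Because no image archive accompanies the study design this package follows,
a synthetic-data module generates both H&E-like scenes with ground-truth
masks and cohort feature tables with prescribed group structure; all tests
run against these.

## Image model and preprocessing

Input images are RGB rasters, nominally 1388 × 1040 px at 0.63 µm/px (10×
objective). Grayscale conversion uses the BT.601 luminance weights
`0.2989 R + 0.5870 G + 0.1140 B`. The weights are standard; the
quantization rule is not implied by them, so the package fixes and documents
round-half-away-from-zero to the nearest integer.

Denoising is a median filter, default window 3 × 3 (the smallest standard
window; configurable) with edge replication at the border. Contrast
enhancement is plain global histogram equalization — the cumulative
histogram remapped onto [0, 255]. The two operations do not commute; the
default order is median-then-equalize (denoise before stretching, so noise
is not amplified), switchable via `equalize_first`.

## Villous segmentation

The gray histogram of an H&E section is bimodal: bright glass background
versus darker stained tissue. `otsu_threshold()` scans all 256 candidate
levels of the histogram and returns the level maximizing the between-class
variance; ties are broken toward the smallest level so results are
deterministic. Note a consequence of that tie-break: when the valley between
modes is empty, the between-class variance is exactly constant across the
gap and the returned level sits at the valley's lower edge, not its center.
Any level in the gap produces the same binarization.

Two interpretation points are left open by the usual verbal description of
this procedure, and both are exposed as configuration:

* **Polarity.** "Villi are the pixels above the threshold" conflicts with
  H&E tissue being *darker* than background. The default `auto` polarity
  takes the class with the lower mean intensity as tissue; both fixed
  polarities are available.
* **Which image is thresholded.** On frames dominated by a narrow-band
  background, equalization stretches the background mode across most of the
  dynamic range, and a valley-seeking threshold then splits background
  noise rather than tissue from background. On the synthetic scenes the
  denoised-image threshold recovers villi near-exactly (the test suite
  enforces Dice ≥ 0.99 and exact component counts) and strictly beats the
  equalized-image threshold on the same scene. The default is therefore
  `threshold_on = "denoised"`, with `"equalized"` available.

Cleanup removes foreground islands below `villous_min_area` (default 64 px)
and fills interior holes below `villous_hole_cap` (default 400 px). The
filled holes are mostly capillary lumina, which belong to the villous for
area accounting; the hole cap keeps genuine inter-villous background open.
Both defaults are stated in pixel units at the nominal 0.63 µm/px scale and
should be rescaled with the optics.

## Capillary segmentation

Capillaries appear in two guises: open lumina (pale, near-background discs
inside the pink stroma) and blood-filled profiles (saturated red). Two
detectors run and their union is taken.

**Lumina** (`morph_capillaries`): the grayscale restricted to the villous
mask is morphologically opened with a 3 × 3 square structuring element
applied `iterations` times (default 8, bounding the detectable lumen
diameter at roughly `2·iterations + 1` px); the residue image-minus-opening
is large at small bright structures and is thresholded (default 40 gray
levels). A plain opening residue also rings around *dark* structures —
nuclear rims, blood, the villous boundary — so the detector additionally
requires a candidate pixel to be brighter than the villous median intensity
plus the threshold; without that gate the false rings dominate the true
lumina. With it, the suite verifies exact per-villous lumen counts on
noise-free renders and capillary Dice ≥ 0.85 on noisy scenes (the
scene-suite driver `analysis/02_segment.R` reports the measured values).

**Blood** (`blood_capillary_mask`): stain unmixing by Beer–Lambert color
deconvolution, `OD = −log10((I+1)/256)` projected through the inverse of a
stain matrix whose columns are the standard published H&E optical-density
vectors (overridable). Blood absorbs outside the hematoxylin direction, so
the eosin-plus-residual density must exceed `density_threshold` (0.15).
Color is confirmed in CIELAB (sRGB → Lab under D65): H&E hues sit at
negative b\* (purple/pink ≈ −8 to −35) while blood red is strongly positive
(b\* ≈ +21), so `b_threshold = 10` separates them with margin.

Both masks are intersected with the villous mask by construction, unioned,
cleaned (`min_area` 4 px) and labeled. Connected components use
8-connectivity by default (4 available); each capillary component is
assigned to the villous holding the majority of its pixels.

## The ten features

Per labeled region: Area = pixel count; Perimeter = number of region pixels
with a background neighbor (4-adjacency by default, the literal
boundary-pixel count); equivalent Diameter = `sqrt(4·Area/π)`, the diameter
of the same-area circle (the only reading of the area-to-diameter formula
that yields a length). Per subject, over all of their images:

| # | feature | aggregation |
|---|---------|-------------|
| 1 | villous count | summed over images |
| 2–4 | villous area / perimeter / diameter | mean over regions |
| 5 | capillary count | summed over images |
| 6–8 | capillary area / perimeter / diameter | mean over regions |
| 9 | capillarization index CI (%) | 100 × total capillary area / total villous area |
| 10 | CI per villous (%) | unweighted mean over villi of 100 × contained capillary area / villous area |

Published group tables of this kind report magnitudes (villous area ≈ 4000,
diameter ≈ 120) that are per-region scale, not slide totals, so per-region
means are the primary aggregation; summed totals are also emitted. Units
are reported in both pixels and micrometers (via `pixel_size`), since such
tables rarely state which was used. The area-weighted mean of per-villous
CI equals CI-from-totals algebraically; the unweighted mean (feature 10) is
a genuinely different summary, which is why both exist.

## The synthetic-data module

`generate_image()` renders: near-white background (244,244,244); villi as
ellipses perturbed by low-order radial Fourier noise (lobulated outlines
without biophysical modeling), eosin-pink stroma (220,140,180) with a ~2 px
hematoxylin rim (90,60,130); capillaries as discs placed strictly inside
villi — pale lumina (242,240,243) or blood-filled (150,40,50), default half
and half, Poisson(4) per villous, radius ~6 px; additive Gaussian noise
(sd 3). Placement is rejection sampling with bounded attempts; an
impossible request fails as an over-dense scene rather than degrading.
Ground-truth masks accompany the image, and the truth records are computed
*from the masks*, so truth areas equal mask pixel counts by construction.

What the renderer deliberately does not emulate: stain texture and
within-structure intensity gradients, syncytial knots, fibrin, infarcts,
section folds, illumination gradients, touching villi. Passing segmentation
tests on these scenes therefore demonstrates correctness of the algorithmic
chain under clean staining geometry, not robustness to real-slide artifacts.

`generate_cohort_features()` draws per-subject feature vectors from normal
distributions with each group's published mean/SD (`default_group_params()`
transcribes the full-cohort n = 40/35 and gestation-matched n = 10/8
presets). Features are drawn independently given group because only
marginal summaries are published; the group mean shift still induces the
between-feature correlation that drives the PCA structure. Negative draws
are floored at 10⁻⁶ (vanishingly rare at the published effect sizes).
Image-scene parameters and cohort parameters are decoupled on purpose:
per-image geometry cannot be inverted from per-subject aggregates.

## Statistics

**FLDA.** For groups with means $\bar{x}_1,\bar{x}_2$ and bias-corrected
pooled covariance $S_{pooled}$ (divisor $n_1+n_2-2$), the discriminant is
$w = S_{pooled}^{-1}(\bar{x}_1-\bar{x}_2)$, the maximizer of Fisher's
criterion $J(w) = w^T S_B w / w^T S_W w$; samples are classified by which
projected group mean their projection $y=w^Tx$ is nearer, i.e. an
equal-prior midpoint threshold (a prior-weighted threshold is a one-line
change; the midpoint is the documented default). A property test checks
$J(w)$ against thousands of random directions, and the direction against
`MASS::lda` as an independent implementation.

**Accuracy ranking.** Features are ranked by single-feature LOO accuracy:
refit without the held-out subject, classify it, average. LOO avoids the
optimism of resubstitution at these sample sizes; resubstitution is
available via `scheme`. Caveat worth knowing: on *exchangeable* groups LOO
nearest-mean classification is pessimistically biased (excluding a subject
shifts its own group mean away from it) with large seed-to-seed spread, so
null-data accuracies well below 50% are expected behavior, not a bug.

**HCA** on z-scored features with Euclidean distance; Ward linkage
(`ward.D2`) by default because it favors the compact two-cluster structure
expected from two separated groups (average linkage available). The
dendrogram is exported as Newick; a flat 2-cluster cut is compared with
group labels by Rand index.

**PCA** is an eigendecomposition of the correlation matrix (z-scored data):
the features mix counts, areas and percentages, so covariance PCA would be
dominated by the largest raw scale. Explained-variance percentages sum to
100 over all components.

**t-tests** are pooled-variance Student tests by default (Welch available),
two-sided, reported at full precision with no multiple-testing correction —
matching the reporting conventions of the tables this mirrors. Note that at
the published means/SDs the implied t statistics are far more extreme than
the p-values printed alongside them in that literature; the package always
reports the values it computes.

## Problem sizes and numerical choices

Scene-suite tests and the analysis drivers use reduced frames (320 × 240 px,
6 villi of ~30 px radius, capillaries ~4 px) — the same renderer and
pipeline defaults at proportional geometry — so a scene generates and
segments in well under a second; the generator default remains the full
1388 × 1040 frame. Cohort-level results in the acceptance script average 50
replicate cohorts. Everything stochastic is seeded; scenes and cohorts are
bit-reproducible for a fixed seed, and segmentation contains no randomized
step. Degenerate inputs fail loudly: constant images (no Otsu threshold),
identical group means (w = 0), collinear features (singular pooled
scatter), zero-variance features (PCA), groups below the minimum size.

## Limitations

The synthetic cohorts inherit every idealization of the normal independent
model — no correlations beyond the group shift, no outliers, no
heteroscedasticity beyond the per-group SDs — so statistics validated on
them are validated as *implementations*, not as robust to real cohort
pathology. The segmentation thresholds (`resid_threshold`, `b_threshold`,
`density_threshold`, island/hole areas) are calibrated to the synthetic
stain palette at 0.63 µm/px and will need retuning for real slides and
other scanners. Touching or overlapping villi are not separated (no
watershed step), and vessel lumen is not distinguished from endothelium.
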