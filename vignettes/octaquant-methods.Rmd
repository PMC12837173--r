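---
title: "Quantifying retinal vasculature in en-face OCTA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal vasculature in en-face OCTA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaquant)
```

## The measurement problem

Optical coherence tomography angiography (OCTA) renders retinal blood flow
as a 2-D en-face image over a square scan field — here 3 × 3 mm² centered on
the macula and 6 × 6 mm² centered on the optic nerve head (ONH). Comparing
vascular integrity between a patient cohort and controls requires turning
each grayscale angiogram into a small set of regional numbers:

1. **Binarization.** A local adaptive threshold separates bright flow signal
   from speckle background. The pipeline routes macula scans to the
   Phansalkar rule, `T = m (1 + p e^{-q m} + k (s/r - 1))`, and ONH scans to
   the Niblack rule, `T = m + k s`, with `m` and `s` the windowed mean and
   (population) standard deviation. Otsu global and per-window local
   variants are available for comparison.
2. **Skeletonization.** The binary vessel map is thinned to 1-px-wide
   centerlines so that the density metric counts capillaries rather than
   vessel caliber; a large arteriole and a capillary contribute equally per
   unit length.
3. **ETDRS sector densities.** The standard ETDRS overlay (circles of 1, 3
   and 6 mm diameter, quadrants split on the ±45° diagonals) is centered on
   the anatomical landmark and the skeletonized vessel density — skeleton
   pixels divided by region pixels — is read per region: 8 regions
   (4 quadrants × inner/outer ring) for the ONH, the 4 inner regions for
   the macula, plus the across-region mean.
4. **FAZ metrics.** The foveal avascular zone outline (traced manually in
   practice; extracted automatically on synthetic data) yields area `A`,
   perimeter `P`, and the acircularity index `P / (2 sqrt(pi A))` — the
   ratio of the FAZ perimeter to the perimeter of the equal-area circle,
   1 for a circle and larger for lobed shapes.
5. **Cohort statistics.** Regional densities enter linear mixed-effects
   models; FAZ metrics enter linear regressions; demographics are compared
   with Welch t and Pearson chi-square tests.

## The mixed model and its contrasts

Laterality (two eyes), quadrant (four per eye) and, for the ONH, ring
(inner/outer) are repeated measurements on a subject. The density model is

```
density ~ diagnosis * quadrant + ring + age + sex + (1 | subject) + (1 | subject:eye)
```

with the inferior quadrant as the reference level and ring omitted for
macula data. The eye-within-subject intercept is the simplest random
structure that respects the nesting; a singular fit triggers an automatic
fall-back to the subject-only intercept (with a warning and a flag in the
result). If the ring fixed effect is not significant at 0.05, inner and
outer densities are averaged per subject × eye × quadrant ("ring collapse")
and the model is refitted.

Post hoc inference is the control − SSD marginal difference at each
quadrant, `-(beta_diag + beta_diag:quadrant)` under treatment coding, with
Satterthwaite degrees of freedom by default (`ddf = "z"` switches to a
normal approximation). A positive estimate means lower density in the case
group. The four raw p-values are Benjamini–Hochberg adjusted; the BH family
is exactly the four quadrant contrasts per site (and separately the three
diagnosis × quadrant interaction terms of the model table), not every test
in an analysis run. Age stratification refits the identical analysis in the
age ≤ 30 and age > 30 strata, and additionally fits the pooled
temporal-quadrant model with a continuous diagnosis × age interaction, so a
finding is not an artifact of one cutoff.

Two boundary conventions differ deliberately: the density-model strata are
≤ 30 / > 30, while the density–RNFL correlation sub-analysis stratifies at
< 30 / ≥ 30 — both following their respective source conventions. The FAZ
regression is unadjusted by default (`adjust = TRUE` adds age and sex).

## The synthetic generator

No OCTA dataset ships with the package; every downstream stage is validated
against synthetic angiograms with known ground truth.

**Image level.** Vessels grow as biased random walks: root walkers start on
the image border (macula, growing inward) or the 1.5-mm optic-disc margin
(ONH, growing outward), take 2-px steps with Gaussian angular jitter
(SD 0.25 rad), branch with probability 0.05 per step, and are stamped with
a 1–3 px disc brush. Growth stops when unmodulated coverage reaches
`base_density` (default 0.12; an unreachable target raises
`"undersaturated"`). A macula scan carves an avascular zone at the center:
a star-shaped outline whose radius is modulated by random 2nd–4th-order
harmonics scaled by `faz_irregularity` (0 = circle), surrounded by a drawn
perifoveal capillary ring so the zone is a bounded component, as in a real
fovea. The background is multiplicative speckle — Gaussian noise on
log-intensity, clipped to [0, 1] — because OCTA decorrelation noise is
speckle-like; `noise_sd` is approximately the coefficient of variation.
Image size defaults to a config knob (512 px for geometry checks, smaller
in fast tests); all geometry derives from `mm_per_px`, never from pixel
counts.

**Regional deficits.** Each walker carries one uniform draw and stamps
pixels inside an ETDRS region only if the draw falls below that region's
multiplier. A vessel therefore either crosses a region at full caliber or
skips it, so mask density *and* skeleton length both scale with the
multiplier, while trajectories and RNG consumption are identical across
multiplier settings — regional density is monotone in the multiplier at a
fixed seed and untouched regions are bit-identical. The price is binomial
noise over the modest number of vessels crossing a region; single-image
ratios are noisy even though the expectation is right. Multipliers above 1
act as 1 (growth is already unmodulated).

**Measurement level.** Statistical calibration needs thousands of cohort
replicates, which image rasterization cannot provide at reasonable cost.
`simulate_cohort_densities()` draws regional densities directly from the
planted measurement model: mean `base_density` (default 0.07 on the
skeleton-density scale), a fractional temporal deficit in the case group
(optionally age-dependent via `deficit_old`), Gaussian subject
(SD 0.008), eye-within-subject (SD 0.004) and residual (SD 0.010)
components, ages truncated-normal (mean 35.7, SD 12.5, range 18–70), and
group-specific male fractions (17/39 and 39/51 by default, echoing the
two-group design the package emulates). Out-of-range densities are clipped
and counted. RNFL thickness is simulated as an affine function of density
plus noise to exercise the correlation analysis.

What passing these tests shows — and does not. The generator reproduces the
*structure* of the measurement problem (bright branching vessels over
speckle, an avascular fovea, a bright disc, nested repeated measures with a
planted regional deficit). It does not emulate calibrated OCTA texture,
projection or motion artifacts, capillary plexus layering, or
vessel-caliber distributions; success on synthetic data validates the
computational contract, not device-specific performance.

## Numerical choices

* **Thresholding is exact by construction.** Windowed sums run on the
  integer 0–255 scale (cumulative sums of integers are exact in doubles),
  so a constant window gives `T = m` with no floating-point dust, and the
  strict `>` comparison deterministically classifies constant images as
  background. Borders are symmetrically mirrored, avoiding the depressed
  local means zero padding would create at the rim.
* **Niblack and speckle.** `T = m + k s` marks a fixed fraction
  (about `P(Z > k)` ≈ 42% at the literature default `k = 0.2`) of any
  vessel-free speckle window as foreground, regardless of the noise
  amplitude — the rule is scale-free. On real angiograms the "background"
  is itself capillary texture, so this matters little; on synthetic scans
  with truly empty background the ONH false-positive floor is visible, and
  the end-to-end planted-deficit check therefore reads the macula
  (Phansalkar) model, whose dynamic-range term keeps dark backgrounds below
  threshold. The per-site defaults remain config-exposed and are echoed
  into every run's metadata.
* **Thinning.** Deletion conditions are the classical two-sub-iteration
  ones (2–6 neighbors, single foreground run, directional gates), but
  deletions are applied *sequentially* in raster order with re-checking: a
  fully parallel sweep erases an isolated 2 × 2 block outright, breaking
  component-count preservation. Endpoints are never deleted (no spur
  pruning); junction clusters are exempt from the unit-width guarantee.
* **Geometry.** Pixel (i, j) has center (j − 0.5, i − 0.5), origin
  top-left, y down — stated once, used everywhere. Annuli are half-open in
  radius and quadrants half-open in angle, so region masks are pairwise
  disjoint and partition the annulus exactly. Nasal/temporal labels flip
  with laterality (OD: temporal on the image left by default); the mapping
  is config-overridable and unit-tested because a silent misassignment
  would invert a temporal finding. The across-region mean is unweighted by
  default (`weighted = TRUE` area-weights it); the two differ because inner
  and outer sectors have different areas.
* **FAZ.** Area uses the shoelace formula and perimeter vertex-to-vertex
  distances on the traced polygon, not pixel-edge counts, which
  overestimate diagonal boundaries by up to √2 and would bias acircularity
  upward. Outlines are stored in pixel units and scaled at metric time.
  Self-intersecting polygons are rejected. The 1.5-mm synthetic disc
  slightly overlaps the inner ETDRS annulus (0.5–0.75 mm), uniformly and
  equally across quadrants.
* **Reproducibility.** Every stochastic entry point takes an integer seed,
  restores the caller's RNG state, and derives sub-stream seeds
  deterministically; identical configurations give byte-identical CSV
  outputs.

## Calibration problem sizes

The suite checks type-I error of the temporal contrast (200 replicate null
cohorts of 40 + 40 subjects; nominal 5%, accepted 2–8%), the age-stratified
pattern (50 replicates of 45 + 45 with a deficit of 0.3 planted only in the
younger stratum; joint young-significant/old-not in > 80%), monotonicity
and approximate unbiasedness of the temporal contrast across deficits 0.1,
0.2, 0.3 (25 replicates each), and oracle agreement for thresholds (50
random images), thinning (200 random masks) and BH adjustment (1000 random
p-vectors). These sizes were chosen to keep Monte-Carlo standard errors
well inside the accepted bands.

## Known limitations

* The speckle model is a stand-in, not a calibrated texture model; no
  quantitative noise spectrum was available to match.
* Walker-level deficit gating makes single-region realized densities
  binomially noisy; tests that assert ratios average a few seeds.
* Niblack's false-positive floor on empty speckle regions (above) limits
  end-to-end ONH effect recovery on synthetic scans; the statistical layer
  is therefore calibrated on measurement-level cohorts.
* The automatic FAZ outline requires an avascular component bounded away
  from the image border; an unbounded fill raises `"unbounded-faz"`,
  mirroring the practice of excluding images in which no FAZ can be
  determined.
* Mixed-model p-values use the Satterthwaite approximation; with two eyes,
  four quadrants and two rings per subject the z approximation differs
  negligibly, but both are exposed.
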