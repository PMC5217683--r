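---
title: "Quantifying morphogenic pathway crosstalk from plate images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying morphogenic pathway crosstalk from plate images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platetalk)
```

## The measurement problem

Developmental signalling pathways — Wnt, TGF-β, BMP — are studied one at a
time, but cells experience their ligands together.  A direct way to ask
whether one pathway's ligand perturbs another pathway's output is a
high-content immunofluorescence screen: treat wells of a multi-well plate
with single ligands and ligand combinations, fix and stain, image several
fields per well, and quantify each pathway's nuclear transcription-factor
readout (β-catenin for Wnt, Smad2/3 for TGF-β, phospho-Smad1/5/8 for BMP)
cell by cell.  A *crosstalk* is a statistically significant change in one
readout caused by another pathway's ligand, alone (cross-activation) or in
combination with the canonical ligand (cross-modulation).

`platetalk` implements this measurement chain end to end:

1. **correction** — dark-frame (detector) subtraction, multiplicative
   flat-field correction estimated per within-well field position from
   uniformly fluorescent reference wells, and quantile background
   subtraction;
2. **segmentation** — global Otsu threshold on the corrected DNA (Hoechst)
   channel, connected components, size and border filters, and per-nucleus
   features (area, total and mean intensity, intensity CV) for every channel;
3. **gating** — restriction to G1/0 cells via a two-component Gaussian
   mixture over total nuclear Hoechst intensity (a proxy for DNA content),
   then ±2 MAD quality windows on nuclear size and Hoechst texture;
4. **response statistics** — per-replicate well medians, normalisation
   anchored at the no-ligand control (0) and the canonical ligand (1),
   min–max scaling for curves, and two-sided Welch t-tests for crosstalk
   calls;
5. **qPCR** — ΔΔCt quantification of threshold-cycle tables against a
   reference gene, with Welch tests on the ΔCt scale;
6. a **synthetic plate generator** that renders TIFF images with known
   ground truth, so that every stage above is validated by parameter
   recovery rather than by eye.

## The statistical model of a response

For one readout channel and one condition, each biological replicate
contributes the *median* total nuclear intensity of its gated cells.  With
replicate medians $m_{c,r}$, control condition $0$ and canonical ligand $1$:

$$\tilde m_{c,r} \;=\; \frac{m_{c,r} - \bar m_0}{\bar m_1 - \bar m_0},$$

so the normalised control mean is exactly 0 and the canonical mean exactly 1.
Because this is an affine transform, the normalised scale is invariant to any
global affine rescaling $a x + b$ ($a > 0$) of raw intensities — gain and
offset drifts between plates cancel.  Crosstalk calls compare replicate
medians by a two-sided Welch (unequal-variance) t-test at per-comparison
$\alpha = 0.05$ with no multiplicity correction by default (a Holm option
exists via `adjust`); the anchor contrast (canonical vs control), every
non-canonical single ligand vs control, and every combination vs both the
canonical ligand alone and the control are emitted, labelled distinctly,
because either combination contrast may be the one of scientific interest.

Medians, not means, summarise wells because single-cell intensity
distributions are skewed and carry segmentation outliers; medians per
*replicate* (not per plate) preserve the biological unit of error.

## Image correction

The camera model assumed (and rendered by the generator) is

$$\text{pixel} = S_{p,\text{ch}} \cdot (\text{scene} + b) + D + \varepsilon,$$

with $S$ a smooth multiplicative shading surface specific to the within-well
field position $p$ and channel, $b$ a scene background, $D$ the per-pixel
detector offset and $\varepsilon$ pixel noise.  Correction inverts this in a
fixed order: subtract $\hat D$ (the pixel-wise mean of dark frames), divide
by $\hat S$ (detector-subtracted reference-well images pooled per position,
lightly smoothed, rescaled to mean 1), then subtract the per-image
background, defined as the mean of pixels strictly below the 0.001 empirical
quantile (linear-interpolation quantile; a constant image falls back to its
minimum).  Whether background subtraction belongs before or after the
division is not dictated by the physics once shading is unit-mean; this
package fixes it *after* the division and asserts the order in a test, so
that the background scalar lives on the same scale as the corrected image.
Negative corrected pixels are kept: clipping would bias nuclear total
intensities upward.

Two numerical choices matter here:

* **Shading smoothing σ** (default: image width / 64).  The smoothing must
  suppress reference-well pixel noise without attenuating the shading field
  itself.  A Gaussian kernel attenuates a spatial frequency $k$ by
  $e^{-k^2\sigma^2/2}$; at σ = width/8 the lowest-frequency component of a
  field spanning the image loses ~25% of its amplitude, which is far worse
  than the noise it removes.  At width/64 the attenuation is below 1% while
  white noise in the pooled reference average is already negligible.
  The parameter is exposed (`smooth_sigma`) for noisier references.
* **Background quantile set**: pixels *strictly below* the quantile are
  averaged; ties (e.g. constant images) fall back to the minimum.  An
  independent full-sort oracle reproduces the estimator exactly in the tests.

## Segmentation and features

Nuclei are bright, well-separated blobs on a dark corrected background, so a
global Otsu threshold on the Hoechst channel followed by connected-component
labelling suffices; no watershed splitting is attempted (the generator
controls overlap, and real clumps are partially handled by the area filter
and the texture window downstream).  Components outside `[min_area,
max_area]` (defaults 10 and 600 px, chosen from the generator's radius
distribution) or touching the image border (truncated totals) are removed and
labels are re-densified from 1.  Per-nucleus, per-channel features are sums
and moments of *corrected* pixel values under the mask; the intensity CV uses
the population SD convention (divide by $N$), which is recorded here because
it changes CVs of small nuclei.  A channel with non-positive within-mask mean
gets `NA` CV but the nucleus is kept.

## DNA-content gating and quality windows

Total nuclear Hoechst intensity is bimodal: the 4N (G2/M) mode sits at twice
the 2N (G1/0) mode.  A two-component univariate Gaussian mixture is fitted by
EM — initialised at the 25th/75th percentiles with equal weights, component
SDs floored at $10^{-6}\,\mathrm{sd}(x)$, log-likelihood trace retained and
asserted non-decreasing — and G1/0 cells are those within the closed interval
mean₁ ± 2 SD₁ of the lower-mean component.  The mixture is fitted per well by
default (staining intensity is a per-well property), with a pooled option.

EM on *unimodal* data is ill-posed: it will happily split a single mode into
two overlapping components, and a "first peak ± 2 SD" window around either
half then discards the bulk of the population.  The fit therefore collapses
to two identical components at the sample moments whenever the fitted
components do not describe two distinct DNA-content modes, using three
complementary symptoms: Ashman's $D = |\mu_2-\mu_1| / \sqrt{(\sigma_1^2 +
\sigma_2^2)/2} < 3$ (components not separated), single-Gaussian BIC ≤ mixture
BIC (no evidence for two components), or fitted mean ratio $\mu_2/\mu_1 <
1.5$ (DNA replication doubles content, so genuine 2N/4N modes sit near 2×;
anything closer is a split mode).  The collapse is flagged in the model
(`collapsed`) and makes re-gating an already-gated population nearly a no-op,
which a test asserts.

Surviving cells then pass ±2 MAD windows (closed intervals) on nuclear area
and on Hoechst intensity CV, with the *unscaled* MAD
$\mathrm{median}(|x-\mathrm{median}(x)|)$ — no 1.4826 consistency factor,
since the windows are stated in raw MAD units.  A zero MAD collapses the
window to the median with a warning.  The windows are computed on the
plate-pooled post-G1 population by default (`qc_per_well = FALSE`): size and
texture are morphological properties shared across wells, and window
estimates from fewer than ~100 cells are dominated by MAD sampling noise.

## What the synthetic generator emulates — and what it does not

The generator's defaults describe one fixed set of study conditions: a
96-well-style plate imaged at 256 × 256 px per field, ~30 nuclei per field
(near-confluent at this magnification), a 70% G1/0 fraction, an 11-bit camera
(values clipped to [0, 2047], stored as lossless 16-bit TIFF), detector
offset 32 a.u. with 2 a.u. read noise plus signal-dependent noise
(SD = 0.3·√signal), scene background 50 a.u., uniformly fluorescent reference
wells at 1200 a.u., and a multiplicative shading field of amplitude 0.3 per
within-well position, histogram-equalised so the shading depth spreads
uniformly over [1 − amplitude, 1].  Treatment effects multiply
transcription-factor totals (baseline lognormal, CV 15%) per condition;
three replicates per condition mirror the standard design.

Several generator choices are deliberate idealisations, made so that the
quality-control contracts are well-posed, and are worth stating:

* **Nuclei are flattened discs** (sigmoid edge, width 0.08·radius), not
  peaked Gaussians.  Interphase nuclei in adherent monolayers are
  plateau-like in projection, and a plateau profile makes the thresholded
  footprint track morphology (≈ πr²) rather than peak brightness — with a
  peaked profile, thresholded area is logarithmically coupled to intensity
  and the ±2 MAD size window clips well over 10% of genuine nuclei no matter
  how the radii are drawn.
* **Constant chromatin concentration within a DNA class**: a nucleus's total
  Hoechst intensity scales with its (pre-G2-enlargement) area times a 6%
  staining factor.  DNA amount is fixed within a class while nuclear volume
  varies, so concentration, not total, is the stable quantity; this yields
  the ~15% G1 total-intensity CV typical of imaging cytometry and keeps
  plateau brightness uniform, so the automatic threshold sits safely below
  every nucleus.  4N nuclei are drawn 1.25× larger in radius, as G2 nuclei
  are.
* **Bounded size and texture laws**: radii are uniform in area on
  [7.5, 9.5] px and per-nucleus chromatin texture (bounded multiplicative
  speckle) follows an arcsine law on [0.08, 0.25].  Healthy-cell QC features
  need light-tailed distributions for a ±2 MAD window to be a *debris*
  filter rather than a tail clipper; heavy-shouldered bounded laws give the
  windows intrinsic margin.  Debris objects (2% of nuclei) are small
  (radius ~4–4.8 px), heavily speckled (texture 0.5), and drawn with a
  2N-like Hoechst total so they *pass* the DNA-content gate and must be
  caught by the size/texture windows — which is exactly what the windows are
  for.

What the generator does **not** emulate: touching or overlapping nuclei
(placement enforces separation, so no watershed is needed or tested),
cytoplasm, S-phase DNA content between the modes, chromatic aberration,
vendor file formats, per-well staining batch effects, and cell motion.
Passing recovery tests on these plates therefore demonstrates that the
*estimators are correct for the stated model*, not that segmentation would
survive dense clumping or that gating would survive a large S-phase
population — on real data those failure modes must be checked with the QC
figures (`plot_gate()`, the gate report counts).

## qPCR arm

Technical triplicates are collapsed by arithmetic mean on the Ct scale (one
missing value of three tolerated with a warning); ΔCt = Ct_target −
Ct_reference within each sample removes sample-wide amplification shifts;
relative expression is $2^{-(\Delta Ct - \overline{\Delta Ct}_{control})}$
with amplification efficiency fixed at 2.0 per cycle (efficiency calibration
is out of scope); tests run on the ΔCt (log) scale where Gaussian assumptions
are defensible, with fold changes reported for display.

## Problem sizes and numerical conventions

The validation suite and the acceptance script use: a 12-well demo plate
(4 conditions × 3 replicates, 2 fields/well, ~740 nuclei) for segmentation,
debris and effect-recovery checks; ~5,000 truth-level nuclei for the gating
fraction; 1,000 statistics-level replicate-triplet experiments for null
calibration; 500 simulations each for crosstalk power and the qPCR round
trip.  Even-n medians use the mid-point convention; all gate and window
boundaries are closed; medians/MADs are computed in double precision; seeds
fan out to stages by fixed offsets so each stage is individually
reproducible, and every output table carries the configuration hash.

## A worked run

```{r example, eval = FALSE}
layout <- default_layout(conditions = c("Wnt3A", "TGFb3", "BMP4"),
                         n_replicates = 3, fields_per_well = 2)
cfg <- run_config(layout,
                  effect_table = c(Wnt3A = 2, TGFb3 = 1.5, BMP4 = 1),
                  design = tibble::tibble(channel = "tf1",
                                          canonical = "Wnt3A"),
                  seed = 1)
res <- run_pipeline(cfg)
res$responses
res$crosstalk
plot_crosstalk(res$crosstalk)
```

## Known limitations

* Otsu thresholding assumes a clearly bimodal pixel histogram; very sparse
  fields or very dim staining will need the exposed size limits and possibly
  a pooled-plate gate.
* The two-component mixture cannot represent S phase; plates with a large
  S-phase fraction will bias the first-peak SD upward and widen the gate.
* Per-comparison α without multiplicity correction mirrors the original
  analysis convention but inflates family-wise error over a large crosstalk
  matrix; use `adjust = "holm"` when the matrix, not a single call, is the
  claim.
* The qPCR module fixes amplification efficiency at 100%; genes with poor
  efficiency need external calibration before the fold changes are
  quantitative.
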