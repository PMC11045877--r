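---
title: "Ratiometric quantification of dual-color BiAD microscopy"
author: "biadquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric quantification of dual-color BiAD microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A dual-color bimolecular anchor detector (BiAD) reports the chromatin
modification state of one genomic locus in one cell. The locus appears as
a bright spot in the marker channel (full-length YPet recruited to the
sgRNA scaffold); the modification appears as fluorescence complementation
of a split near-infrared fluorophore (IFP2.0) at that same spot, formed
only when the anchor and a modification-reader module meet. Spot
brightness in the marker channel is dominated by the local number of
sgRNA binding sites, which at real target loci spans from a few dozen to
more than a thousand repeats. Absolute BiAD intensity is therefore
uninterpretable on its own; the meaningful quantity is the BiAD signal
*relative* to the marker signal at the same spot.

For spot $s$ in a cell with nuclear region $n$, with mean intensities
$M$ (marker channel) and $B$ (BiAD channel),

$$ r_s = \frac{B_s - B_n}{M_s - M_n}, \qquad
   \bar r_{\mathrm{cell}} = \frac{1}{|S|}\sum_{s \in S} r_s $$

where $S$ is the set of valid spots of the cell. Background subtraction
uses the mean intensity over the whole nuclear region per channel, and
$\bar r_{\mathrm{cell}}$ — one value per cell — is the unit of all group
statistics.

## Segmentation model

Two intensity thresholds on the marker channel define the regions of
interest, mirroring the manual workflow this analysis standardizes:

* **Nucleus**: pixels at or above the low threshold; the largest
  4-connected component is kept and interior holes are filled (nuclei can
  contain dim interior pixels; 4-connectivity avoids bridging to debris
  through diagonal touches).
* **Spots**: pixels at or above the high threshold inside the nucleus;
  8-connected components (spots are compact; diagonal pixels belong
  together), filtered by a minimum area (default 4 px) to suppress
  shot-noise singletons, ranked by mean marker intensity with ties broken
  by larger area and then earlier raster order, and capped at the
  **six brightest spots per cell** — the convention the assay's
  statistics are defined on.

Thresholds can be supplied per cell (`ThresholdPair`, the faithful manual
mode, recorded in the output for audit) or derived automatically for batch
operation: Otsu's method on the marker channel for the nucleus, and a
configurable quantile (default the 99.5th percentile) of within-nucleus
marker intensity for the spot threshold. One numerical refinement matters
in practice: marker spots can be an order of magnitude brighter than the
nucleus while covering only a few percent of its area, and those few
pixels dominate Otsu's between-class variance, pushing the "nucleus"
threshold up between nucleus and spots. The implementation therefore clips
the marker image at its 98th percentile before computing the Otsu
threshold; the spot quantile is then taken on the unclipped values.

The nuclear mean includes spot pixels: the workflow measures the whole
thresholded nucleus as one ROI. With spots a few percent of the nuclear
area this biases ratios by a comparable few percent at most, and not at
all when all of a cell's loci share one true ratio (both channels are then
affinely related, and the bias cancels exactly). For analyses that need
exact per-spot recovery with heterogeneous ratios,
`quantifyCell(exclude_spots_from_background = TRUE)` recomputes the
background over the nucleus minus all spot masks; the option is off by
default to match the standard workflow.

## Sign conventions and guards

Background-corrected BiAD intensities are **not clamped at zero**. A
binding-deficient detector produces spots whose BiAD intensity fluctuates
around the nuclear background; clamping would fold that noise upward and
bias the null away from zero, corrupting exactly the contrast (wild type
vs mutant) the assay relies on. Negative per-spot ratios participate in
the per-cell mean.

The ratio denominator is guarded: spots whose corrected marker intensity
falls below $10^{-6}$ of the marker channel's dynamic range are flagged
invalid and excluded from aggregation (with a QC record), never replaced
by zero. By construction spots are far brighter than the nuclear
background in the marker channel, so the guard only trips on degenerate
inputs.

## Allelic and control normalizations

For X-inactivation analyses the inactive X (Xi) is identified by an
immunostain territory (e.g. H3K27me3): the stain channel is thresholded
within the nucleus (Otsu or manual), and a spot is labeled Xi when at
least half of its pixels fall inside the territory — the boundary is
inclusive, so exactly 0.5 is Xi. Each spot's ratio is then divided by the
mean over that cell's Xa spots, anchoring Xa at exactly 1 per cell so Xi
values read as fold enrichment.

For treatment comparisons, per-cell signals are divided by the arithmetic
mean of the control-detector cells *within the same treatment arm*
(at least 3 control cells required per arm; a near-zero control mean
refuses normalization rather than producing unstable fold changes).

## Statistics

Cells are the statistical unit; replicates are recorded and colored in
plots but pooled for testing, matching the assay's reporting convention.
Two groups are compared with a two-tailed unpaired t test — Welch's form
by default, since nothing guarantees equal variances between detector
variants, with Student's form available. Three or more groups use one-way
ANOVA with Tukey's HSD post test. Boxplots use type-7 (linear
interpolation) quantiles with whiskers at the most extreme observations
within 1.5 IQR of the box.

## The simulator: what it emulates and what it does not

`simulationConfig()` describes a cell population; `simulateCell()` renders
one cell and its ground truth; `simulateExperiment()` writes a full
multi-condition dataset (TIFFs, sample sheet, truth table) with
deterministic per-cell seeds.

The rendered structure: an elliptical nucleus (default semi-axes 40 × 30
px in a 128 px frame) over dark background (5 counts), marker base 100 and
BiAD base 40 inside the nucleus; 2–4 loci (default 3) with marker spot
amplitude `marker_gain × copy_number` — a **linear brightness model**,
an assumption, since the real mapping from repeat count to spot brightness
is not characterized — with default copy numbers 45/160/392 spanning the
low end of the documented 45 to >1,000 repeat range; BiAD spot amplitude
equal to marker amplitude times the true ratio
(`detector_efficiency × modification_fraction × biad_gain`, times
`biad_enrichment` on Xi loci); an optional stain territory, the configured
fraction of nucleus pixels nearest a randomly placed center, containing
the Xi loci and clear of the Xa loci; whole-cell transfection dropout that
zeroes BiAD amplitudes at the configured probability; and camera noise as
Poisson resampling plus Gaussian read noise (default sd 5) plus an
optional offset, clipped at zero.

Spots come in two shapes. **Top-hat** (default): flat discs of radius 4
px, which make noiseless recovery exact and are used throughout the test
suite. **Gaussian**: PSF-like profiles for realism; recovery is then
approximate because thresholded masks capture a profile-dependent fraction
of the amplitude. The simulator deliberately omits optical aberrations,
z-dependent PSFs, photobleaching, chromatic shift, spectral bleed-through
(real acquisition windows were chosen to avoid it) and nucleus shape
irregularity — so passing tests demonstrate correctness of the
*quantification chain*, not robustness to every optical artifact of real
data.

`simSpotSNR()` computes the per-pixel BiAD signal-to-noise ratio of the
dimmest configured locus (amplitude over shot-plus-read noise standard
deviation); the noise-recovery tests run at SNR ≈ 10, which a copy number
of 58 at the default gain produces, chosen analytically from the noise
model.

## Problem sizes and numerical checks

The test suite validates, among others: exact recovery of configured
ratios 0/0.25/0.5/1.0 on noiseless top-hat cells to 10⁻¹⁰ relative error;
agreement of projection, ROI means and spot selection with brute-force
loop oracles on over a hundred random images; recovery of a 0.5 ratio
within 5% from 50 noisy cells at SNR 10, across 20 seeds; a significant
(p < 0.01) wild-type vs mutant contrast with a mutant null within ±0.05 of
zero across 100 simulation replicates of 30 + 30 cells; Xi enrichment 2.0
recovered within 10% from 50 allelic cells; a 0.3 dropout rate recovered
within its binomial 99% interval over 500 cells; and t-test p-values
matching a 10⁵-permutation oracle. These sizes keep the whole suite at a
few minutes on a laptop while leaving comfortable statistical margins.

Determinism is part of the contract: a configuration seed fixes the full
simulated output byte-for-byte, and identical pipeline runs produce
identical tables (`%.17g` serialization makes CSV round-trips lossless).

## Known limitations

* The analysis operates on maximum-intensity projections, as the workflow
  it implements does; true 3D segmentation is out of scope.
* The nuclear-background convention (spot pixels included) and the
  absence of a minimum spot size in the original macro are not
  documented; both behaviors are implemented with the stated defaults.
* Replicates are pooled, not modeled hierarchically; with strong batch
  effects a mixed model would be more appropriate than the pooled t test.
* The copy-number-to-brightness map is linear by assumption; only ratio
  *invariance* to copy number, which holds regardless of the map's shape
  under the ratiometric model, is essential to the conclusions.
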