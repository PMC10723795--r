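---
title: "Quantifying nucleolar stress: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleolar stress: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoscore)
```

## The measurement problem

The nucleolus is a membrane-less organelle organized around ribosomal DNA. Its
fibrillar center (FC) holds the rDNA-bound transcription machinery (marked by
UBF), and its granular component (GC) holds late ribosome-assembly factors
(marked by nucleolin or NPM1). Nucleoli are polymorphic — different in number,
size, and shape from cell to cell — so no single geometric feature separates
healthy from stressed nucleoli. What *is* consistent under stress is a
redistribution of the two marker classes: GC proteins dissolve into the
nucleoplasm, while FC proteins stay bound to rDNA or condense further.

The **nucleolar normality score** turns that contrast into one per-cell
number. With integrated (summed) intensities over masks,

$$
\mathrm{score} \;=\;
\frac{I^{GC}_{nucleolar} \,/\, I^{GC}_{nucleoplasmic}}
     {I^{FC}_{nucleolar} \,/\, I^{FC}_{nucleoplasmic}} .
$$

The numerator falls when the GC marker disperses; the denominator rises when
the FC marker condenses. Both effects push the score down, and the
ratio-of-ratios construction cancels per-channel gain: multiplying any single
channel by a positive constant leaves the score unchanged (this invariance is
asserted to $10^{-12}$ in the test suite). The nucleoplasmic intensity is
defined by exact subtraction, $I_{nucleoplasm} = I_{nucleus} - I_{nucleolar}$,
so the two compartments always partition the nucleus.

## Segmentation procedure and parameters

Segmentation follows the high-content convention of a two-stage mask:

1. **Nuclei** from the DNA counterstain: rolling-ball background subtraction
   (large radius), global threshold at 10% of the subtracted image maximum,
   hole filling, removal of border-touching objects and objects outside an
   area range, consecutive relabeling.
2. **Nucleoli** from the FC-marker channel: rolling-ball subtraction (smaller
   radius), Gaussian smoothing with SD 0.7 px, then *per nucleus* a threshold
   at 40% of that nucleus's (max − min) intensity span. Components under
   4 px are discarded as noise. Each nucleolus carries a parent pointer to
   its nucleus, and masks never cross nuclear boundaries, so editing one
   nucleus can never change another's nucleoli.

Parameter notes, with defaults in `seg_params()`:

* `nucleus_threshold_frac = 0.10` and `nucleolus_threshold_frac = 0.40` are
  the published plugin constants; the approximate "~10%" is implemented as
  exactly 0.10 and left configurable.
* Threshold comparisons are `>=` (a pixel exactly at the threshold is
  foreground). The tie-break matters because min–max thresholds frequently
  hit exact pixel values on synthetic images.
* The nucleus threshold uses the maximum of the *background-subtracted*
  image; this choice is recorded here because the alternative (raw maximum)
  is equally consistent with common practice.
* Rolling-ball radii have no published values beyond "large" (DNA) and
  "small" (marker channels). Defaults are 50 and 10 px, suited to
  high-magnification images where nuclei span hundreds of pixels. **The
  marker-channel radius must exceed the nucleus diameter in units of the
  image at hand**: a ball that fits inside the nucleus classifies the
  nucleoplasmic plateau itself as background and destroys the intensity
  bookkeeping the score needs. `synthetic_seg_params()` therefore scales both
  radii to the synthetic nucleus size (3x and 2.5x the nucleus radius).
* The nucleus size range default is `[1000, 30000]` px²; a range is part of
  the published procedure but its bounds are not, so these are conventional
  values exposed in the configuration.
* Connectivity defaults to 8 (the ImageJ-style convention) and can be set
  to 4. Component labeling uses `EBImage::bwlabel` plus a union–find merge
  of diagonally adjacent components for the 8-connected case.
* Hole filling applies to nuclei only. Nucleoli legitimately exclude
  FC-negative interior, especially in the dissolution phenotype.
* Intensities are measured on the background-subtracted but **unblurred**
  channels; the blurred image exists only to define masks. Measuring on
  blurred data would leak intensity across compartment boundaries.

### Rolling-ball background

The rolling ball is implemented in-package as grayscale opening with a
ball-height structuring element ($z = \sqrt{r^2 - d^2}$), with two standard
refinements: the background is estimated on a 3×3-mean-filtered copy (without
this, the min-type operations latch onto the lowest noise excursions and
systematically underestimate the background of photon-noisy images), and
radii above 16 px run on a block-minimum downsampled grid with bilinear
interpolation back, as high-content plugins do. The estimate is clamped to
lie at or below the image, so the subtraction is always non-negative and
structures narrower than the ball diameter are preserved. No installed
package provides rolling-ball subtraction; EBImage's flat-disc opening serves
as an independent oracle in the tests where the two operators must agree
(interiors of wide flat regions).

## Cells without nucleoli

A cell with no detected nucleoli has no defined score (its nucleolar
intensity is zero and the FC ratio degenerates). Such cells receive `NA`,
are excluded from field and well means, and are counted in a QC column
(`n_unscored_cells`). The alternative — scoring them zero — would inject an
arbitrary value into well means; sensitivity to the choice is covered by the
aggregation tests, which verify that unscored cells change the QC tally but
not the mean.

## Screen analysis

Aggregation is two-stage, matching the screen design of many fields per well:
per-field means of defined scores, then per-well means of field means.
Vehicle (DMSO) wells are pooled across plates by default to estimate the
vehicle mean and sample SD; per-plate pooling is available for robustness
checks. A compound well is a **hit** when its score falls more than $k = 2$
vehicle SDs below the vehicle mean. One-sided-below is the default because
nucleolar stress only lowers the score and every hit in the original screen
lay below the control; a two-sided mode exists. The rule is invariant under
common affine rescaling of the scores, so raw and vehicle-normalized scores
give identical calls — which also renders moot the question of which scale
the SD cutoff was computed on.

Compound categories (`both`, `10_only`, `1_only`, `none`) are a pure function
of the per-concentration calls and partition the library. Target-class
enrichment among hits uses the hypergeometric upper tail (one-sided Fisher
test): the probability of drawing at least the observed number of class
members when drawing the hit set from the library without replacement. This
is the natural exact test for hit-versus-library composition; the test suite
pins it against an explicit `choose()` enumeration and, on small libraries,
against full subset enumeration. P-values are reported raw (the screen's
p < 0.05 and p < 0.001 tiers are raw); a Benjamini–Hochberg flag exists but
defaults off.

The per-well false-positive calibration of the $k$-SD rule is
$\Phi(-2) \approx 0.0228$ under the null, and the acceptance checks verify
the empirical rate on 10 000 simulated null wells against exact binomial
bounds, applying the rule with the generator's true vehicle parameters
(estimating them from a finite vehicle pool would add threshold noise that is
not part of the calibration statement). Note that a compound tested at two
concentrations has roughly twice the per-well rate of being called a hit at
either one; false-positive accounting in the tests is therefore per well.

## FRAP recovery model

Traces are double-normalized:

$$
F_{norm}(t) = \frac{F_{roi}(t)-F_{bg}(t)}{F_{whole}(t)-F_{bg}(t)} \cdot
\frac{\bar F_{whole,pre}-\bar F_{bg,pre}}{\bar F_{roi,pre}-\bar F_{bg,pre}},
$$

which subtracts the extracellular background, cancels acquisition
photobleaching exactly (bleaching multiplies ROI and whole-nucleus signal
alike), and scales the pre-bleach level to 1. The post-bleach curve is fit
with the bounded-amplitude two-component recovery

$$
F(t') = F_0 + A_1(1-e^{-k_1 t'}) + A_2(1-e^{-k_2 t'}),
\qquad A_i \ge 0,\; k_i > 0,
$$

the standard form when only "two-component exponential recovery" is
specified. The half-time $T_{1/2}$ is defined on the fitted **composite**
curve — the numeric root of $F(T) = F_0 + (\text{plateau}-F_0)/2$ — rather
than on either component alone; the component rates are reported alongside.

Numerical choices, all deterministic (no random restarts):

* Initialization: $F_0$ from the first post-bleach point, plateau from the
  mean of the final 10% of points, rate seeds from a coarse log-spaced grid
  with amplitudes solved by non-negative linear least squares at each grid
  point; refinement by bounded Levenberg–Marquardt (`minpack.lm`).
* Components are canonicalized $k_1 \ge k_2$.
* Two-exponential fits are notoriously degenerate, so a single-component
  model is always fit as well; the single model is adopted (and flagged)
  when the two-component rates collapse ($k_1/k_2 < 1.5$), when the
  two-component optimizer fails, or when the single model matches its
  residual sum of squares — which also makes the $A_2 \to 0$ limit reduce
  exactly to $T_{1/2} = \ln 2 / k$.
* Non-convergence is reported honestly: the `converged` flag is part of the
  fit object, group summaries use converged fits only, and comparisons for
  groups with fewer than two converged fits are skipped with notice.

Group comparisons use Welch's unequal-variance t-test, the appropriate
default for per-cell half-time sets of unequal spread.

ROI extraction and image registration happen upstream of this module; it
consumes trace tables (time, ROI mean, background mean, whole-nucleus mean,
bleach frame index).

## Phosphosite filtering rules

The proteomics module implements only the tabular derivation rules; spectral
counts, dNSAF abundances, and differential-abundance FDRs are inputs.
Abundance classification: enriched/depleted at |LogFC| > 1.5 with FDR < 0.05.
Site filtering: sites on proteins with a significant abundance *decrease*
(FDR < 10⁻⁴, negative LogFC) under any listed drug are removed (both drugs
share the plotted axes; a per-drug mode exists); sites with fewer than two
spectra in *either* untreated replicate are removed — the stricter
per-replicate reading of the rule, with a per-total mode behind a flag.
Untreated/treated spectral-count ratios replace a zero on either side with
0.1 to avoid division by zero; the replacement is applied symmetrically,
since the published axes are symmetric, though only the treated-side zero is
stated explicitly. Records with zero counts everywhere are dropped with
notice.

## What the synthetic generator emulates — and what it does not

`generate_field()` renders nuclei as uniform disks (radius 20 ± 2 px in a
256×256 field, five per field) and four marker-redistribution phenotypes:

| phenotype | FC geometry | GC dispersal $f$ | other |
|---|---|---|---|
| normal | 3 cores, r = 4 px | 0 | — |
| canonical_stress | 2 peripheral caps, r = 3 px | 0.5 | 30% of nucleoplasmic FC recruited into caps |
| metabolic | 2 shrunken cores, r = 3 px | 0.1 | GC excess scaled to 60% |
| dissolution | 1 random-walk string, 2 px wide | 0.95 | — |

Each nucleus carries a fixed total marker "excess" (GC 30 000, FC 22 500
arbitrary units) on top of uniform nucleoplasmic baselines (20 and 30 per
px) and a DNA level of 120 per px over an extracellular offset of 8; noise
is Poisson photon noise plus Gaussian read noise (SD 3) — the standard
fluorescence camera model. These values were chosen once to give
signal-to-background ratios typical of well-exposed immunofluorescence and
analytic scores near 1.8 (normal), 1.0 (metabolic), 0.3 (canonical), and
0.07 (dissolution), reproducing the qualitative ordering and severity of the
four stress states. The generator returns exact noiseless per-compartment
sums and the analytic score per cell, which is what "ground truth" means in
every oracle test.

The generator deliberately does **not** simulate optics (no PSF, no depth
effects), touching or overlapping nuclei, intra-nuclear texture,
condensation-dependent marker brightness, or liquid–liquid phase-separation
dynamics. Passing the pipeline tests on synthetic fields therefore
demonstrates correctness of the measurement arithmetic, the segmentation
rules, and the stress ordering under the stated noise model — not robustness
to crowded fields, focus drift, or staining artifacts in real screens.

`generate_plate()` models the screen at the score level: vehicle and non-hit
wells draw true well scores from Normal(1, 0.05²); planted hits are shifted
down by a chosen multiple of the vehicle SD at 10 µM (and at 1 µM for
"both"-category hits); per-cell scores scatter with SD 0.15 over 200 cells in
4 fields per well; the default library mirrors the screened one (1180
compounds, 83/69 planted hit split). `generate_frap_trace()` forward-
simulates raw intensities whose normalization recovers the model exactly,
with defaults ($A_1=A_2=0.35$, $k_1=0.4\,s^{-1}$, $k_2=0.04\,s^{-1}$,
$F_0=0.3$) giving a composite half-time near 4.6 s, the scale reported for
GC-marker recovery in living cells.

## Problem sizes and determinism

The shipped checks use 20 fields per condition for imaging statistics, 200
traces for FRAP recovery, 10 000 wells for null calibration, and libraries up
to 25 for enrichment enumeration — sizes at which every check's sampling
error is far from its decision boundary while the whole suite runs in
minutes on one core. All stochastic steps flow from explicit integer seeds;
`generate_*` functions restore the caller's RNG state, and identical
parameters give bit-identical output.

## Known limitations

* The rolling-ball downsampled path is an approximation for radii > 16 px
  (matching plugin practice); tests bound its deviation from the exact
  computation.
* Touching nuclei are not split (no watershed); the generator never produces
  them, and real confluent fields would need an upstream splitter.
* The per-cell score distribution in `generate_plate()` is Gaussian; real
  per-cell scores are right-skewed. Well-level statistics are insensitive to
  this at the simulated depths.
* End-to-end pipeline scores on noisy synthetic fields sit a few percent
  below the analytic truth (residual background at nucleus rims and mask
  imperfection); the acceptance output reports this deviation explicitly
  rather than calibrating it away.
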