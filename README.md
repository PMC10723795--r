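# nucleoscore

Quantification of **nucleolar stress** from high-content fluorescence
microscopy, for labs screening compounds or perturbations that disrupt
ribosome biogenesis.

The nucleolus assembles around ribosomal DNA: its fibrillar center (FC,
marked by UBF) holds the rDNA-bound RNA Pol I machinery, and its granular
component (GC, marked by nucleolin or NPM1) holds late ribosome-assembly
factors. Under stress the GC marker disperses into the nucleoplasm while the
FC marker stays bound or condenses. Because nucleoli are too polymorphic for
any geometric feature to separate healthy from stressed cells, the package's
core readout is the per-cell **nucleolar normality score** — a ratio of
compartment ratios over integrated (summed) intensities:

```
            I_nucleolar(GC) / I_nucleoplasm(GC)
  score  =  -----------------------------------
            I_nucleolar(FC) / I_nucleoplasm(FC)
```

GC dispersal lowers the numerator, FC condensation raises the denominator:
both push the score down. The construction cancels per-channel gain, so the
score needs no intensity calibration.

## What the package does

* **Image I/O** — multipage 16-bit TIFF fields with named channels, z-stack
  sum/max projection, manifest CSVs for multi-field acquisitions.
* **Segmentation** — nuclei from the DNA counterstain (rolling-ball
  background subtraction, threshold at 10% of the image maximum, hole
  filling, border and size-range exclusion) and per-nucleus nucleoli from
  the FC channel (0.7 px Gaussian blur, threshold at 40% of each nucleus's
  min–max span, objects < 4 px discarded).
* **Scoring** — per-cell compartment intensities, normality scores,
  single-channel nucleolus/nucleoplasm ratios (e.g. POLR1A retention), and
  per-field intensity summaries with vehicle normalization (5-EU / Y10b
  style readouts).
* **Screen analysis** — field→well aggregation, pooled vehicle statistics,
  hit calling at a k-SD cutoff (default: 2 SD below the DMSO mean,
  one-sided), compound categories across two concentrations, and
  hypergeometric target-class enrichment among hits.
* **FRAP** — double normalization with exact acquisition-bleaching
  correction, constrained two-component exponential recovery fits with a
  deterministic grid-seeded optimizer, composite-curve half-times, and
  Welch-test group comparisons. Fits are classed objects with
  `print/coef/predict/fitted/residuals/plot` methods.
* **Phosphoproteomics filters** — abundance classification (|LogFC| > 1.5,
  FDR < 0.05), spectral-count ratios with the 0 → 0.1 replacement, and the
  decreased-phosphosite filtering rules (protein-decrease exclusion at
  FDR < 10⁻⁴, ≥ 2 spectra per untreated replicate).
* **Synthetic data** — a ground-truthed generator for fields in four stress
  phenotypes (normal, canonical stress caps, metabolic shrinkage,
  dissolution with FC strings), screening plates with planted hits, and
  FRAP traces — so every stage is testable without microscope data.

## Worked example

Generate a canonical-stress field (RNA Pol I inhibition: FC caps, partial GC
dispersal), segment it, and score every cell:

```r
library(nucleoscore)

gf   <- generate_field(phenotype_params("canonical_stress", seed = 11))
sp   <- synthetic_seg_params(gf$params)
nuc  <- segment_nuclei(gf$field$channels$dapi, sp)
noli <- segment_nucleoli(gf$field$channels$ubf, nuc, sp)
meas <- measure_cells(gf$field, nuc, noli, c("ncl", "ubf"),
                      bg_radius = sp$nucleolus_bg_radius)
meas$score <- normality_score(meas, "ncl", "ubf")
meas[, c("nucleus_label", "n_nucleoli", "nucleus_area_px",
         "nucleolar_area_px", "score")]
#>   nucleus_label n_nucleoli nucleus_area_px nucleolar_area_px     score
#> 1             1          2            1292                60 0.3208193
#> 2             2          2            1145                58 0.3023446
#> 3             3          2            1468                58 0.3167993
#> 4             4          2            1058                58 0.3031036
#> 5             5          2            1021                54 0.3072273
```

The measured scores (~0.31) sit close to the generator's analytic
ground-truth score for this phenotype (0.295) and far below a normal field
(~1.8): canonical stress drops the score several-fold. A FRAP example:

```r
tr  <- generate_frap_trace(noise_sd = 0.02, seed = 1)
fit <- fit_recovery(normalize_trace(tr))
fit
#> <frap_fit> F0=0.2937  A1=0.3412 k1=0.4508/s  A2=0.3743 k2=0.04075/s
#>   plateau=1.009  T_half=4.461 s  rms=0.0172  converged=TRUE
```

The fitted composite half-time (4.46 s) recovers the generating model's
4.51 s from a noisy trace. See the vignette
(`vignettes/nucleolar-stress-quantification.Rmd`) for the model details,
parameter rationale, and the generator's scope.

A thin command-line dispatcher over the same pipeline functions ships at
`inst/cli/nucleoscore.R` (subcommands `simulate`, `score`, `screen`, `frap`,
`phospho`).

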