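---
title: "Quantitative peritoneal histomorphometry: models and methods"
author: "peritomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative peritoneal histomorphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peritomorph)
```

## The measurement problem

The peritoneum — the membrane used as the exchange surface in peritoneal
dialysis — is quantified here through a small set of histomorphometric
endpoints measured on immunostained tissue sections: the density and
morphology of blood and lymphatic microvessels, the thickness of the
submesothelial connective-tissue zone, the layered arrangement of vessels
below the mesothelial monolayer, the integrity of the mesothelial surface,
and age-dependent reference centiles for all of these. The dual-stain
design does the vessel-class bookkeeping: CD31 marks all endothelium
(blood and lymphatic), podoplanin marks lymphatic endothelium and
mesothelial cells but not blood endothelium, so per sample

$$ \text{blood count} = \max(N_{\mathrm{CD31}} - N_{\mathrm{podo}},\, 0). $$

Because no patient images accompany the published reference values, every
measurement in this package is validated as a *parameter-recovery
experiment*: a seeded generator draws synthetic sections whose ground
truth is set to a published cohort value, and the full measurement chain
must recover that value. The `recover_*()` functions (and
`scripts/acceptance.R`) run exactly these experiments.

## The synthetic-tissue generator

`generate_section()` renders single-channel intensity images (row 1 = the
peritoneal surface; depth increases down the rows) at a default pixel
scale of 0.25 µm/px, matching a 40× whole-slide scan and giving a
realistic discretization error for 1–2 µm endothelial walls. The default
analyzed area is 1.44 mm², the cohort median analysis area.

* **Vessels** are annular cross-sections: outer radius drawn from a
  normal distribution (default mean 5, sd 1 µm), wall thickness fixed at
  the group median, lumen radius = outer − wall. A configurable fraction
  (default 10%) is rendered *collapsed* — filled discs without a lumen.
  Counts are Poisson with mean density × area; centres follow a Poisson
  process laterally and, in depth, a three-component normal mixture at
  the published layer medians 36/96/192 µm. Published dispersions are
  interquartile ranges; they are converted to normal scale by
  σ ≈ IQR/1.349. Positions are resampled (up to 100 attempts) until rings
  are separable with a 2 µm clearance, which keeps the segmentation
  contract simple; merged-ring splitting is exercised separately.
* **Mesothelium** is a 3 µm band along the surface, interrupted in
  ~50 µm blocks so that a configurable fraction of the surface (default
  21%, the published denuded proportion) lacks the monolayer. Podoplanin
  marks this band in addition to lymphatic vessels.
* **Submesothelium** ends at a lower boundary (fat/muscle/fascia in the
  structural code map) whose depth varies laterally as a
  median-preserving linear wedge (±15%) plus a whole-period sinusoid
  (±3%) — enough roughness to make transect placement matter without
  moving the median.
* **Mast cells** are small discs (2.5 µm radius) at Poisson density
  12.9/mm².
* **Intensity model**: positive objects at 0.8 on a 0.1 background with
  additive Gaussian noise (sd 0.05), clamped to [0, 1]. The default
  classification thresholds (negative < 0.3 ≤ weak < 0.5 ≤ medium <
  0.7 ≤ strong) are calibrated to this model and exposed per stain, since
  commercial positive-pixel intensity ranges are validated per staining
  and unpublished.

What the generator does *not* emulate: DAB/hematoxylin colour chemistry,
tissue folds, uneven illumination, scanner artifacts, partial-volume
intensity at object edges, or biological vessel shapes beyond circular
cross-sections. Recovery of a published value therefore demonstrates that
the measurement chain is unbiased under the stated geometric and
intensity model — not that it would be unbiased on stained glass.

The published per-vessel medians are not mutually consistent with
circular annuli (an area of 57 µm² implies r ≈ 4.3 µm while a perimeter
of 43 µm implies r ≈ 6.8 µm, and endothelial area ≈ vessel area implies
a wall far thicker than the printed 1.29 µm). The default radius
distribution is therefore a compromise; wall thickness, the only
morphometric endpoint validated against a printed value, is matched
exactly.

## Segmentation and morphometry

`detect_vessels()` thresholds the channel, labels connected positive
components (components below 12 µm² are treated as noise — the smallest
published median capillary is ~48 µm²), and recovers each lumen by hole
filling. A vessel with lumen below 4 px² is flagged collapsed: it counts
toward density but is excluded from all shape metrics. Components
touching the image border are flagged and likewise excluded from shape
metrics. A component containing more than one distinct lumen is split by
one round of watershed on the distance transform of its filled mask.

Perimeters use a Crofton-type digitization correction: naive counting of
exposed 4-neighbour pixel edges overestimates smooth contours by a factor
4/π (~27%), so edge counts are scaled by π/4. On digitized circles of
radius ≥ 2 µm at the default scale this estimator is accurate to well
under 1%.

Per-vessel wall thickness has no published formula; it is computed as
endothelial area divided by the mean ring length (mean of outer and
endoluminal perimeter), which equals exactly r_out − r_in for a perfect
annulus — the identity anchoring its tests. Endothelial surface per
tissue volume is Σ(endoluminal perimeter) × t / (analyzed area × t);
the section thickness t cancels algebraically and the implementation is
verified to be exactly independent of it. Relative endothelial area is
the positive endothelial pixel area (collapsed vessels included) as a
percentage of the analyzed area, consistent with the positivity-based
workflow; the positivity denominator is the analyzed tissue region, not
an arbitrary canvas. Published per-sample summaries are medians, so
`summarize_sample()` reports medians over non-collapsed, non-border
records.

On the podoplanin channel a 15 µm surface margin is masked before
counting so the mesothelial band is not segmented as a vessel. This can
swallow the rare lymphatic vessel lying almost entirely within the
margin (&lt;3% of lymphatics at the infant layer geometry) — a small,
known, conservative bias.

## Layered structure

Submesothelial thickness is the median of ≥ 5 perpendicular transects
(default 7, evenly spaced with 5% lateral margins) from the bottom of the
mesothelium to the first deeper tissue class. A separate superficial
"compact zone" is not modelled, as it could not be delineated in healthy
tissue.

Vessel depths are clustered into k = 3 ordered layers. Two methods are
provided. Seeded k-medians with depth-tercile initialization is the
simple, fully deterministic option — but hard partitioning is *not* the
default, for a quantitative reason: at the published layer geometry the
deep layer is five times wider than the superficial one, the components
overlap heavily, and the hard-assignment median of the middle cluster
converges to ~123 µm when the true middle-layer median is 96 µm (a +28%
bias that persists at any sample size). The default `method = "gmm"`
fits a three-component unequal-variance normal mixture by EM and reports
each component's median (= mean); this estimator is consistent and
empirically unbiased at the published geometry. The fraction of vessels
that sit ambiguously between layers is reflected in the mixture
responsibilities rather than forced into a hard label.

The layer-depth recovery experiment (`recover_layer_depths()`) draws 300
depths per replicate from the published mixture and reports the median
recovered middle-layer depth over 40 replicate draws — the same
cohort-median design as the other recovery experiments; a single draw of
300 depths estimates the middle layer with ~13 µm standard error, so
replication measures the method's central tendency rather than one
draw's luck.

## LMS reference centiles

Reference curves use the λ–µ–σ (LMS) method: a Box-Cox power L(t),
median M(t) and coefficient of variation S(t), smooth in transformed age
t = log(age + 0.25 y), with z = ((y/M)^L − 1)/(L·S) standard normal
(log form at L = 0, to which the transform is continuous). The log age
axis concentrates resolution in infancy, where the peritoneal measures
change steepest. The three curves are natural-spline functions fitted
jointly by maximum likelihood with fixed degrees of freedom (L: 2, M: 4,
S: 3, including intercepts) — the reference analysis this reproduces
does not fix the LMS smoothing, so these conventional, config-exposed
defaults are this package's own choice, and fixed-df
regression splines stand in for penalized splines at the same equivalent
degrees of freedom. M and S are modelled on the log scale, which
enforces positivity everywhere. Reported centiles default to the
conventional 3rd/10th/25th/50th/75th/90th/97th set.

Numerical notes: optimization is BFGS with a Nelder-Mead fallback;
starting values come from a log-scale linear fit for M, its residual
spread for S, and L = 1. The Box-Cox switch uses |L| &lt; 1e-7, and the
percentile inverse clamps 1 + L·S·z away from zero. As with any ML
spline fit, the outer few percent of the age range carries extra
variance; curves are meant to be read where the reference data live.

## Cohort statistics

`compare_groups()` reproduces the published decision procedure:
Shapiro-Wilk per group at α = 0.05 decides between one-way ANOVA (all
groups normal; summaries as mean ± SEM) and Kruskal-Wallis (otherwise;
median (IQR)). "Assessed graphically" has no computational analogue, so
the Shapiro-Wilk decision stands alone and is logged per group.
Categorical tables use chi-square, switching to Fisher's exact test when
any expected cell is below 5. `correlate()` picks Pearson when both
margins pass Shapiro-Wilk, Spearman otherwise. No multiple-testing
correction is applied, matching the source analysis. The seven age
groups are half-open on the pediatric side; the published notation
leaves (40, 41) years unassigned between "18–40" and "41–60", so ages
there go to the older group and the assignment is annotated.

## Experiment sizes and determinism

The recovery experiments use the study conditions directly: 14 infant
sections of 1.44 mm² at 0.25 µm/px for the density and endothelial-area
experiments, ≥ 200 rings for wall thickness, 15 sections for thickness
transects, 30 for mast-cell counting, 10 omental sections of 0.5 mm²
(the omental regime is about vessel crowding, not area, so a smaller
canvas suffices at 434 vessels/mm²). Every random draw descends from a
single integer seed; identical seeds give bit-identical ground truth,
images and results. Unit tests run on smaller canvases (0.02–0.8 mm² at
0.25–1 µm/px), where every property tested is scale-checked
(areas/perimeters stable to &lt; 2% under grid refinement for objects
≥ 5 µm).

## Known limitations

* The published relative endothelial area (5.8% in infants) is
  geometrically incompatible with the published infant capillary density
  and per-vessel endothelial area (~1.2%); which pixel population entered
  the printed percentage is not stated. The recovery experiment keeps the
  printed density and solves the ring calibre (wall 4 µm, outer radius
  ≈ 12.4 µm) so that the true endothelial fraction equals the printed
  percentage; the measurement side (positivity) is geometry-agnostic.
* Dual-stain differencing gives per-sample *counts*, not per-object
  blood/lymph labels; blood-class morphology therefore summarizes the
  CD31 channel (predominantly blood vessels) and lymphatic-class
  morphology the podoplanin channel, mirroring the published tables.
* Nerve fibres are not segmented, omental arteriolar media thickness is
  out of scope, and no object-level registration between adjacent
  sections is attempted.
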