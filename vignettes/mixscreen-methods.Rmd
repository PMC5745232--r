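---
title: "Quantifying subpopulation drug response in mixed tumor cultures: models and methods"
author: "mixscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subpopulation drug response in mixed tumor cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixscreen)
```

## The problem

Early cultures derived from tumor biopsies are mixtures: cancer cells grow
together with tumor-derived stromal fibroblasts and, in feeder-supported
protocols, on a monolayer of irradiated foreskin fibroblasts. A bulk
viability readout (ATP luminescence) reports the whole well and cannot say
whether a drug acted on the cancer cells. The assay this package
reimplements resolves that by imaging two channels per well — a nuclear
stain (Hoechst 33342) counting every cell and a cytokeratin-8/18
immunofluorescence channel marking cells of epithelial origin — and scoring
every nucleus as CK8/18-positive (cancer) or CK8/18-negative (stroma,
feeders). Dose–response curves and IC50s are then fitted *per
subpopulation*.

No raw screen images are publicly available, so the package ships a
ground-truthed simulator of the whole assay. Every downstream stage —
segmentation, scoring, counting, normalization, fitting, endpoint logic —
is validated against the simulator's known truth.

## The growth-and-kill model

Each population $k$ in a well is parameterised by an initial count
$n_{0k}$, a doubling time $T_k$ (infinite for irradiated feeders), and, if
drug-sensitive, Hill parameters $(\mathrm{IC50}_k, h_k, E_{\max,k})$. The
fractional drug effect at dose $d$ is

$$E_k(d) = E_{\max,k}\,\frac{d^{h_k}}{d^{h_k} + \mathrm{IC50}_k^{h_k}},$$

and the expected count after $t$ hours is

$$n_k(t) = n_{0k}\,2^{\,(t/T_k)\,g_k\,(1 - E_k(d)) \;-\; \delta_k E_k(d)\, t/\ln 2},$$

where $g_k$ is a media-dependent growth multiplier and $\delta_k \ge 0$ an
optional effect-proportional death rate. With $\delta_k = 0$ (the default)
the drug is purely cytostatic: a saturating dose arrests the population at
its day-0 count. A positive $\delta_k$ produces curves that drop below the
day-0 level, as cytotoxic responses do. Sampled well counts are Poisson
around the expectation — plain counting statistics.

Media scenarios modulate two things: `TCM` (tumor culture media, which
contains EGF and insulin) multiplies the operative IC50 of EGFR/ALK
inhibitors (default shift 4x) and accelerates growth (default 1.25x for the
cancer population); `TCM_minus_E_I` keeps the growth advantage but has
shift 1, mirroring the observation that removing EGF and insulin restores
the R10-media drug response. The shift and growth values are package
choices of plausible magnitude — the source assay reports the direction of
these effects, not their size.

### Study conditions

The default conditions are those of the assay: 250 cancer cells plated on
~500 irradiated feeders per 384-well; 12-dose series in 3-fold dilution
from 3333 nM (the printed doses 3.33 µM, 370 nM and 41 nM all lie on this
grid); quadruplicate treatment wells plus quadruplicate vehicle and day-0
wells; drug plates fixed when the untreated cancer population has at least
quadrupled (about two doublings — 96 h at the default 48-h doubling time).
Three ready-made scenarios carry published IC50s as simulator ground truth:
`MGH021-2` (ceritinib 90 nM, crizotinib 1300 nM), `MGH051-1` (ceritinib
53 nM, crizotinib 60 nM) and `MGH092-1` (lorlatinib 2 nM, crizotinib
166 nM, ceritinib 268 nM).

## Image formation

Cells are placed uniformly in the field (one site covers the imaged well
area) with a minimum centre separation of 9 px where geometrically
feasible, sequentially across populations so that no population overlaps
another; an interior margin keeps whole cells in frame. Densities above a
packing limit (75% nominal nuclear area) are rejected. Nuclei are rendered
as super-Gaussian blobs $A\,e^{-(r/R)^{2m}}$ — flat core, soft shoulder —
with the point-spread softness folded analytically into the shoulder order
$m$ rather than applied as a separate convolution pass. Marker-positive
cells additionally emit a cytoplasmic annulus (radius 1.5x the nucleus,
dimmer over the nucleus) in channel 2; marker-negative cells emit nothing
there, reflecting that the CK8/18 cocktail does not stain fibroblasts.
Both channels receive additive background and Gaussian read-out noise and
are clipped to the bit depth (16-bit by default, 512x512 px).

Default nucleus diameters are 10 px (cancer) and 10.5 px (feeders, mildly
oval). These sit at the lower edge of a realistic 10–14 px band on
purpose: at the densest study condition (1000 cancer + 500 feeders after
two doublings in one field) larger nuclei would push nominal density past
the ~60% regime in which watershed segmentation remains reliable.
Drug-affected cancer cells can be rendered larger (`sizeEffect`), mirroring
the enlarged morphology of drug-treated cells.

What the simulator does *not* emulate: uneven illumination, focus drift,
staining heterogeneity within a population, apoptotic debris, cell
clumping beyond the separation model, and multi-site stitching artefacts.
Passing tests therefore demonstrate correctness of the quantification
logic, not robustness to every real-microscope artefact.

## Quantification

**Local background** is the 12th percentile of each 64-px block,
bilinearly interpolated. A low quantile, not the median, because in dense
fields cells cover half the block and a median sits on the cells
(measured: the median background estimate rose 20-fold in dense fields and
destroyed the detection mask).

**Nuclear segmentation** thresholds the channel at background +
`intensityAboveBackground` (default 1000 counts), fills holes smaller than
the minimum nucleus area, splits touching nuclei by a distance-transform
watershed (peak prominence tolerance 0.2 px), and keeps regions whose
equivalent diameter lies in `[minWidth, maxWidth]` = [5, 22] px. Nuclei
touching the border are excluded; the simulator's interior margin means
this does not bias synthetic benchmarks. Blank or saturated fields return
zero regions plus a QC flag rather than an error.

**Marker scoring** thresholds channel 2 the same way (default 600 counts)
with a morphological opening. Each nucleus is grown by a 3-px
cytoplasm-search radius (contested pixels go to the nearest nucleus) and
called positive when at least half of its searched region lies in the
marker mask. The 0.5/3 px rule was chosen over a looser 0.3/5 px variant
after direct measurement: in dense co-cultures the looser rule called ~38%
of feeders positive through neighbouring cancer cytoplasm; the tighter one
keeps the false-positive rate near 9% while retaining ~99.9% of true
positives.

Measured fidelity on simulated fields: at day-0 density (~23%) detection
and classification are essentially perfect; at the densest condition
(~55%) overall detection recall and precision stay above 0.95, while the
negative class degrades (recall ~0.9, ~10% misclassified positive) because
merged neighbours are preferentially resolved in favour of the more
numerous positive class. Counts match ground truth exactly only on sparse
noiseless fields — at 55% density physically touching blobs make exact
counting impossible for any segmenter.

## Dose–response estimation

The per-drug positive and negative condition series (vehicle wells as the
dose-0 condition) are fitted with the four-parameter logistic

$$f(d) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}{1 + (d/\mathrm{IC50})^{h}}.$$

Three estimator choices matter and are worth stating plainly:

* **Log2 response scale.** Counts of an exponentially growing culture are
  $n(d) = n_0 2^{D(1-E(d))}$ after $D$ doublings — *not* logistic in $d$.
  A 4PL fit to linear counts lands systematically ~40% below the true IC50
  at $D \approx 2$. On the log2 scale the same model is exactly logistic
  with midpoint at the true IC50, so `fitReport()` fits
  $\log_2(\mathrm{count}+1)$ by default. `fit4PL()` itself is
  scale-agnostic.
* **Day-0 bottom anchor for partial curves.** A fully growth-arrested
  population sits at its day-0 count, which the day-0 plate measures
  directly. When a series traverses less than 80% of the span between its
  top and $\log_2(\text{day-0 baseline})$ — so its own lower shoulder lies
  beyond the tested doses — the bottom is fixed at that anchor. Without
  it, such partial curves (crizotinib at 1300 nM against a 3333 nM top
  dose) wander along the shallow-hill/deep-bottom ridge; simulations went
  from 12/20 to 20/20 runs within 25% of truth with the anchor. Complete
  curves keep a free bottom, which tracks genuine floors, including
  cytotoxic ones below day-0.
* **Unweighted condition means.** Inverse-variance weights built from
  quadruplicate SDs (a chi variate with 3 df) are noisy enough to
  destabilise exactly those partial curves; fits are unweighted by
  default, which on the log2 scale is close to optimal anyway since
  Poisson noise is near-homoscedastic there.

Initialisation: top = max mean, bottom = min mean (or the anchor),
hill = 1, and the IC50 at the log-interpolated dose where the means cross
the half-response level; the IC50 is bounded in [min dose/10, max
dose x 10] and the reported value is the curve's inflection concentration
(relative IC50). Degenerate inputs (constant response, <4 distinct doses,
optimizer failure, inverted asymptotes) return `converged = FALSE`, never
an error.

The bulk-viability surrogate is a weighted sum of positive and negative
counts per well. In pure cultures its fitted IC50 matches the
positive-count IC50; adding insensitive proliferating fibroblasts
compresses its dynamic range while leaving the positive-count curve in
place — the quantitative form of the argument for per-population readouts.
Flatness of the negative series is tested by regressing counts on log10
dose and checking that the slope's 95% CI covers zero.

## Cohort statistics

Success rates are `100 * finished / total`, displayed rounded
half-away-from-zero as in the published table (e.g. 6/16 = 37.5 → 38).
`fisherExact2x2()` is a full hypergeometric enumeration: with margins
fixed, the two-sided p-value sums the probabilities of all tables whose
probability does not exceed the observed table's (probability-mass method,
with a 1e-7 relative tie tolerance). The test suite sweeps every 2x2 table
with total ≤ 40 against an independent brute-force enumerator and
cross-checks `stats::fisher.test`. Odds ratios are the sample
cross-product ratio; zero cells are flagged, never silently corrected.

## Problem sizes and reproducibility

Simulation studies in the test suite use the study conditions above:
image-based IC50 recovery runs two seeded replicates of each published
scenario (each a full 104–152-well plate), and count-level recovery runs
the IC50 x hill grid at 12 doses x 4 replicates. The acceptance script
reports the median over 10 seeded image-pipeline runs of the MGH051-1
ceritinib plate. All randomness flows from explicit integer seeds;
identical configuration and seed reproduce byte-identical plates,
manifests and ground-truth tables.

## Known limitations

* The negative-class counts degrade ~10% at the densest wells; curve tops
  of heavily growing mixed wells are correspondingly compressed, and the
  image-derived negative series acquires a small positive dose trend
  (feeders are recovered better as cancer cells are killed off), so the
  formal flatness test is a count-level statement.
* The anchored fit assumes the day-0 plate shares the drug plate's
  seeding; a systematic plating offset between plates would bias partial
  curves.
* Media effects (growth multiplier, IC50 shift) are scalar multipliers;
  real media effects are drug- and culture-specific.
* The simulator's noise model is additive Gaussian plus Poisson counts; it
  does not emulate shot-noise-limited imaging or illumination gradients.
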