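---
title: "Methods: single-bean hyperspectral aroma prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-bean hyperspectral aroma prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beanspec)
```

## The problem

Short-wave-infrared hyperspectral imaging measures a full reflectance
spectrum (~900–2500 nm) for every pixel of a scene, so single roasted
coffee beans can be characterised non-destructively. The chemistry of
interest — the relative abundance of volatile aroma compounds measured
by headspace GC–MS as percentages of total peak area — is present at
concentrations far too low for direct NIR quantification. What the
spectra *do* see are the biochemical precursors and roast intermediates
(Maillard substrates, sugars, chlorogenic acids, water/oil matrix) that
covary with groups of volatiles sharing a formation pathway. The
modelling target is therefore indirect: multi-response PLS regression
from bean spectra to compound (or compound-group) abundances, good
enough for screening and for sorting beans into aroma-contrasted
batches, not for analytical quantification.

## The synthetic study

No single-bean HSI + GC–MS dataset of this kind is deposited publicly,
so the package generates one with known ground truth. The generator is
the package's testing instrument: its defaults *are* the study
conditions, chosen once and fixed.

**Design.** 25 batches × 10 beans (the standard single-bean study
layout), each bean scanned on two sides with independent noise and
scatter. 20% of batches are Robusta (batches are single-species, as
commercial lots are); the paper-style species contrast is imposed as a
+0.5 SD shift on the Maillard/pyrazine factor and −0.5 SD on the
aldehyde factor for Robusta. The 20% default is our assumption about a
mixed commercial sample set; the fraction is configurable.

**Chemistry.** Four latent roast factors with unit variance drive the
50-compound roster: Maillard/N-heterocycle (pyrazines, pyridines,
pyrroles), Strecker (aldehydes), sugar caramelisation (ketones, furans,
alcohols, esters), and phenolic/acid. Factors have batch-level and
bean-level components (intraclass correlation 0.3 — batches differ by
origin and processing, but beans within a batch still vary). Compound
`j` of class `c(j)` has abundance
`mu_j · max(0, 1 + 0.15·z_{f(c)} + h_c + e_j)` with a small class-level
wobble (`sd` 0.015) and per-compound noise (`sd` 0.015); the means
`mu_j` give a medium-roast pattern (pyrazines ≈ 25–30% of total area).
This makes compounds of one class strongly positively correlated,
classes sharing a factor moderately correlated, and everything
non-negative. Profiles are closed to 100%, exactly as GC–MS relative
peak areas are.

**Spectra.** Bean absorbance is a smooth roast baseline plus, per
factor, a loading spectrum built from Gaussian bands at the published
assignment wavelengths (1435, 1450, 1680, 1940, 1975, 2050, 2100, 2276,
2300 nm; widths 20–60 nm), scaled by the factor score, then distorted by
a multiplicative lognormal gain and additive offset (the scatter that
SNV provably removes) plus i.i.d. noise, and returned as reflectance
`10^(−A)` clipped to (0, 1]. The loading spectra are orthogonalised to
the baseline over the band grid so that the per-spectrum standard
deviation used by SNV is constant to first order in the factors; without
this, SNV itself would bias factor recovery.

**The `signal_r2` dial.** Each factor is split into a spectrally
expressed part and an unexpressed remainder:
`z = sqrt(s)·v + sqrt(1−s)·w` (+ species shift, expressed scaled by
`sqrt(s)`). The expressed share `s` is the *ceiling* on the
cross-validated R² attainable by any model of a factor-driven response,
which makes parameter recovery testable: at `s = 0.70` the pyrazine
class sum cross-validates at R² ≈ 0.68–0.70 (slightly below the ceiling
because of profile closure, the small idiosyncratic terms, parsimonious
latent-variable selection and finite-sample cross-validation), and at
`s = 0` the spectrum carries no chemical information at all, so any
positive cross-validated R² would indicate leakage.

**Imaging.** Beans are rendered as 12 × 8 pixel ellipses on a dark tray,
with 5% relative per-pixel jitter, converted to raw counts through
`raw = dark + R·(white − dark)` with structured dark/white means and
~100 reference frames (the white reference is modelled at exactly 100%
reflectance so a noiseless run round-trips to < 1e-6).

**What the generator does not emulate.** Radiative transfer and
scattering physics, roasting kinetics, pixel-to-pixel spatial
correlation within beans, detector nonlinearity, or GC–MS measurement
error structure. Passing tests therefore demonstrate the correctness and
calibration of the *pipeline*, not field performance on real scans.

## Processing choices

* **Calibration** uses the standard push-broom convention
  `(raw − dark)/(white − dark)` with frames averaged first; reflectance
  is clipped to [1e-4, 1.5] — the ceiling tolerates white-reference
  overshoot, the floor protects `log10(1/R)`.
* **Segmentation** thresholds the 1300 nm band by Otsu's method and
  labels 8-connected components (≥ 20 pixels), ordered top-to-bottom
  then left-to-right. 1300 nm sits in a quiet spectral region where the
  bean/tray contrast is large.
* **Band trimming** drops bands below 950 nm and above 2450 nm (noisy
  detector edges) before modelling; configurable.
* **Pre-treatments** follow the usual comparison set: `log1R`
  (absorbance only), `snv` (SNV of absorbance) and `sg2`
  (Savitzky–Golay 2nd derivative of absorbance, window 11 points, order
  2 — standard for ~6 nm sampling; neither is universal, so both are
  configurable and recorded). The derivative and SNV are applied to
  absorbance, treating `log(1/R)` as the base representation. The two
  scanned sides are averaged *before* pre-treatment; SNV does not
  commute with averaging, so the order is fixed and asserted by a
  regression test.

## Regression and validation

PLS2 (NIPALS) mean-centres both blocks without variance scaling — the
common chemometrics default; a `scale_y` flag enables response
autoscaling for users whose responses span orders of magnitude.
Cross-validation uses 20 segments, assignment balanced (sizes differ by
at most one) and stratified by batch so every held-out segment samples
across batches — the conservative anti-leakage choice given batch-level
random effects; centering is recomputed per fold, and the per-spectrum
pre-treatments involve no cross-bean statistics. R² is reported as the
coefficient of determination on pooled held-out predictions (not a
squared correlation — the two differ), RPD as sd(reference)/RMSECV with
the cross-validated error.

The latent-variable count implements the "lowest possible" rule as a
testable criterion: the smallest count whose response-averaged RMSECV is
within 2% of the global minimum. Averaging raw RMSECV across responses
weights large-scale responses more; with responses on commensurate
scales (class percentage sums) this is harmless, and the rule is exposed
per-model for anything else. On noiseless low-rank data the rule finds
the true rank exactly; on the synthetic study it typically selects 3–5
latent variables.

Numerical edge cases: a zero-norm NIPALS weight (exhausted X block)
stops extraction early and reports the achieved component count;
cross-validation folds that stop early reuse their deepest model for
larger counts; perfect cross-validated predictions report RPD = Inf;
zero-variance references are an error rather than a silent NaN.

## Segregation trial

Beans are ranked by a model-predicted attribute and the top and bottom
`ceiling(0.10·n)` selected (ties broken by bean id; an all-tied vector
is flagged as degenerate). High/Low/Remainder batches are compared on
their *true* class and descriptor sums — per-bean profiles rather than
the pooled batch measurement a wet-lab trial would use, which is
statistically equivalent at this scale — by one-way ANOVA and Tukey HSD
at α = 0.05, summarised by a greedy insert-and-absorb compact letter
display assigned in descending group-mean order. If every group has zero
internal variance the comparison is flagged as exact separation and
letters follow the mean ordering. Because pyrazines and the other
N-heterocycles share a latent factor (common biochemical origin),
sorting on predicted pyrazines co-shifts the heterocyclic-N sums — the
qualitative pattern a real trial shows. Profile closure keeps class sums
mildly nonlinear in the spectrum, so even a noise-free linear model can
swap beans right at the selection boundary; the trial is about
enrichment, not identifying an exact bean set.

## The compound roster

The packaged roster transcribes the 50 identified volatiles with their
chemical classes and odour-activity annotation codes exactly as
tabulated, including two chemically surprising class labels (phenol
under "Heterocyclic N", 2-formylpyrrole under "Phenolic"); a
`chemically_corrected = TRUE` variant reassigns those two, and all
census-style checks are defined against the verbatim roster. The
compound→descriptor mapping (and the positive/negative valence used by
the valence ratio) is *not* part of the published table; the package
ships a default mapping assembled from each compound's canonical
literature descriptors (pyrazines → nutty/roasted, acids → sour,
guaiacols → spicy, …) and treats it as replaceable configuration —
descriptor-level results are mapping-relative. Multi-descriptor
compounds contribute their full area to every descriptor they carry
(odorant-series convention), so descriptor sums deliberately do not
partition the total.

## Problem sizes and calibration checks

The test suite and acceptance script run the full 25 × 10 design for
parameter recovery (pooled over ten replicate studies, since a single
250-bean study estimates R²cv only to about ±0.03), twenty seeded
replicates for the segregation property, 10^4 null simulations for the
Pearson and ANOVA type-I calibration (5% ± 0.6%), and a noiseless
single-batch scene for the imaging round trip (max absolute deviation
< 1e-6, ≥ 99% of bean pixels recovered). These sizes were chosen so
each property is estimated with sampling error well inside its
acceptance band.

## Known limitations

* Real-data performance claims cannot be made from the synthetic study;
  the generator's factor structure is an assumption, not an estimate
  from data (bean-to-bean variance structure is unpublished).
* The ENVI reader covers the subset the package writes (BSQ, float32/64,
  little-endian) — it is not a general ENVI implementation.
* PLS2 with a handful of responses and ~250 samples is the intended
  regime; no sparse or kernel variants are provided.
* Descriptor-level (odorant-series) results depend entirely on the
  packaged descriptor mapping; swap in your own mapping file for other
  sensory conventions.
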