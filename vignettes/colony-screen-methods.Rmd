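---
title: "Methods: colony-array screen statistics in colonyscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colony-array screen statistics in colonyscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical methods: the
models behind each stage, the assumptions they lean on, the parameters a
user might want to move, and the places where a design decision had to be
made because the underlying experimental platforms leave them open.

## The experiment the package models

A strain library is pinned onto solid-medium plates in a 1536-position
(32 × 48) array. Each 2 × 2 block holds three adjacent replicate colonies of
one library strain and, in the block's fourth position, a colony of a
designated spatial control strain — so controls form a regular lattice
covering one quarter of the plate. Plates are grown under a basal condition
and a stress condition (the motivating screen used 150 mM acetic acid),
imaged every 20 minutes for 96 hours, and the whole experiment is repeated
in two independent runs, giving six replicate measurements per strain and
condition.

## Growth curves and feature extraction

`growth_model()` is a three-parameter logistic with an explicit lag:
flat at `n0` until `lag`, then
\[
N(t) = \frac{K\,n_0\,e^{r(t-\mathrm{lag})}}{K + n_0\,(e^{r(t-\mathrm{lag})}-1)},
\qquad r = \ln 2 / \mathrm{GT}.
\]
The platforms this mimics do not publish a curve model; logistic-with-lag is
the minimal shape exhibiting the three phenotypes the analysis consumes
(lag, generation time, yield). Non-growth is encoded as an infinite
generation time and a flat curve.

`extract_features()` estimates the maximal specific growth rate as the
largest least-squares slope of `log2(value)` over a sliding window (default
5 points, i.e. 80 minutes at 20-minute sampling) — the standard
model-free estimator. Generation time is the reciprocal slope; lag is where
the tangent line through the max-slope window returns to the initial log2
level (clipped at zero), a definition chosen over threshold crossing for
its noise robustness; yield is `max(value) − value[1]`. A colony is a
non-grower when its total fold change stays below 2 **or** its generation
time exceeds 48 h — the cap mirrors the screen's own convention that
colonies doubling slower than 48 h under stress count as completely
inhibited. On noiseless logistic curves sampled every 20 min the estimator
recovers GT within 0.2% and lag within 0.001 h across GT ∈ [1, 12] h and
lag ∈ [0, 24] h (the acceptance script re-measures this), comfortably
inside the 2%/one-sampling-interval envelope we consider acceptable.

Smoothing (`smooth_curve()`) is a 5-point median filter followed by a
3-point moving average, shrinking at the ends; it is spike-robust and
leaves a noiseless logistic essentially untouched. Neither upstream
platform specifies its smoother; this one is declared as the package's
contract. Calibration from raw pixel proxy to OD is a hook
(`calibrate_curve()`) with the identity map as default, since no published
calibration exists for the screen's instrument.

## Spatial normalization

The control lattice carries the plate's spatial bias. `fit_control_surface()`
fits, at every grid position, a Gaussian-kernel-weighted quadratic
polynomial (bandwidth 4 grid units, i.e. two control spacings) to the
control growers' log2 GT, then applies two *twicing* passes: the smoother is
re-applied to the control-position residuals and the result added back.
Twicing removes the leading orders of kernel smoothing bias, so a smooth
noiseless bias field is reproduced nearly exactly — a plain local mean at
this bandwidth leaves ~3 × 10⁻² log2 units of curvature bias, a local
quadratic ~10⁻³, and the twiced local quadratic ~3 × 10⁻⁴, which is what
lets injected basal offsets be recovered to better than 10⁻³ under a
0.3-amplitude bias field. With per-colony noise present the extra passes
add a little variance; with 384 controls per plate this is negligible
against the noise floor.

The log strain coefficient is `LSC = log2(GT) − log2(surface)`. Plate-wise
batch correction subtracts the median LSC of **all** colonies on the plate
(controls included, non-growers excluded) — valid because the vast majority
of library strains behave like the control, so the plate median estimates
the batch offset rather than biology. Correction is applied per
(plate, run, condition); whether the motivating study pooled runs before or
after this step is not stated, and per-run correction is the conservative
choice because it also absorbs run-specific offsets.

The log phenotypic index pairs replicate `k` of run `j` in the stress
condition with replicate `k` of run `j` in basal medium (same plate
position; the pairing is not stated by the study, which only shows
per-replicate LPIs): `LPI = LSC_stress − LSC_basal`. Because both members
of a pair sit at the same position of plates with their own fitted
surfaces and medians, plate-constant distortions cancel; a strain slow in
both media has LPI 0.

## Hit calling

The null model treats every per-replicate LPI lying inside the
interquartile range of the complete data set as chance variation. Quartiles
use the linear-interpolation convention (R type 7); the IQR-restricted
values (bounds inclusive) form the null sample. The "complete data set" is
read as replicate-level values pooled over all strains — the
strain-mean-level alternative is available via `null_on = "strain_means"` —
because the replicate-level reading gives the two-sample test a
well-defined second sample.

Each strain's replicates (3–6; strains with fewer than 2 are flagged
untestable, excluded from the multiple-testing family and reported
unchanged) are compared to the null sample with Welch's two-sample
two-sided *t* test (hand-implemented; the test suite pins it to the
reference implementation at 10⁻¹⁰). The wording of the study's null
hypothesis also admits a one-sample reading against the null mean;
`welch_mode = "one-sample"` implements it, two-sample is the default.
P values get Benjamini–Hochberg step-up adjustment (also hand-implemented
and oracle-pinned), and calls additionally require clearing the **control
envelope**: the interval between the minimum and maximum of the control
strains' mean LPIs, so that no call is smaller than what neutral guides
exhibit. Sensitive: mean LPI above the envelope and adjusted P ≤ 0.1;
tolerant: below and adjusted P ≤ 0.1. Strains growing in basal medium whose
stress replicates all failed are called sensitive without statistics; their
gene-level summary reports complete inhibition rather than a percent
change. Percent change in generation time is `(2^LPI − 1)·100`, the
conversion used for the gene tables.

## The synthetic-data generator

`simulate_screen()` draws, per physical plate (plate × run × condition), a
smooth multiplicative bias field — a random quadratic polynomial plus three
radial Gaussian bumps of fixed width (sd 12 grid units), rescaled to span
exactly `[1 − a, 1 + a]` — plus a batch offset (log2-normal, sd 0.02) and
per-colony log2 GT noise (sd 0.05). Bumps of width 12 were chosen once as
the realistic scale: plate artifacts (drying, temperature, pinning
pressure) vary over plate quadrants, not between neighbouring positions.
Strain effects are injected as log2 offsets: basal offsets N(0, 0.03) for
all library strains, stress effects N(−0.2, 0.05) for the tolerant fraction
(5%) and N(+0.3, 0.05) for the sensitive fraction (5%); 0.2% of strains are
completely inhibited under stress only and 1% in basal medium, echoing the
motivating screen's observation that ~1% of its library failed under basal
conditions. Twenty library strains carry neutral guides (zero effect) and
define the control envelope, alongside the spatial control strain. The
noise magnitudes are assumptions, not estimates — the study does not report
its instrument's noise floor — and they were fixed so that the
per-replicate spread of control LSCs is ≈ 0.05 log2 units, a plausible
value for a well-run solid-medium screen.

What the generator deliberately does **not** emulate: pixel-level imaging,
colony-neighbour competition, non-multiplicative (e.g. additive or
rank-distorting) spatial artifacts, run-specific layout rearrangements, and
heavy-tailed or correlated noise. Tests passing on these simulations
therefore demonstrate the statistical machinery under the stated generative
model, not robustness to every failure mode of real plates.

## Numerical and edge-case choices

- Quartiles: type 7 (linear interpolation); IQR bounds inclusive.
- Plate median with an even count: mean of the middle two.
- Welch with two zero-variance samples: p = 1 if the means agree, else 0.
- BH: untestable strains' NAs never enter `m`; adjusted values are capped
  at 1 and monotone by construction.
- Non-grower LSCs are missing values, excluded from surfaces, medians and
  null building; they are never silently dropped — unpaired positions are
  kept with NA LPI and counted in a warning.
- `classify_strain()` is a pure function; `call_screen()` output is
  invariant to input row order.
- Ties in the max-slope search resolve to the earliest window.
- The surface fit requires ≥ 10 usable control growers per plate and fails
  loudly otherwise.

## qPCR module

Relative expression is `2^{ΔCT}` with
`ΔCT = geomean(CT_refs) − CT_target`, the geometric mean taken on the cycle
scale over the reference genes, and amplification fixed at 2.0 per cycle
(the motivating experiments reported primer efficiencies of 96–102%). Note
one subtlety: the geometric mean on the cycle scale is only approximately
equivariant to a constant CT shift (exactly so when the reference CTs are
equal); the residual is below 0.01 cycles for references two cycles apart,
far below qPCR measurement noise. Group comparison follows the
F-test-then-t-test recipe: a two-tailed variance-ratio F test at
`alpha_var = 0.05` (both the two-tailedness and the threshold are choices
the source protocol leaves open) selects the pooled- or unequal-variance
two-tailed t test; percent change is computed against the pooled control
mean.

## Problem sizes used by the tests and acceptance script

Unit tests run mostly on 16 × 24-grid plates (96 strains); the acceptance
checks use one full 32 × 48 plate for spatial normalization, ten fully-null
4-plate screens (1536 strains each) for type-I calibration, and three
4-plate screens with injected effects for recovery/FDR — sizes chosen as
the smallest at which every estimate is stable (the empirical FDR of a
single screen, in particular, fluctuates with the random width of the
20-control envelope, so calls are pooled over three screens before the rate
is formed).

## Known limitations

- The spatial estimator assumes a smooth multiplicative bias; sharp
  discontinuities (e.g. a damaged pin row) would need a robust/segmented
  variant.
- The IQR null assumes most strains are phenotypically neutral; in a
  library where most guides have effects the null sample would be
  contaminated and calls conservative-to-wrong.
- The envelope gate inherits the sampling noise of however many control
  strains exist; with 20 controls its width varies noticeably between
  screens, and that variance propagates into the empirical FDR.
- Gene-level aggregation counts called guides; it performs no meta-analytic
  p-value combination.
- `read_deposited_tables()` ingests per-strain replicate LPI tables (CSV /
  TSV / xlsx) for re-calling deposited screens; column mapping is the
  caller's responsibility since deposits vary.
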