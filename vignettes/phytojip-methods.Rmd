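---
title: "Methods and design notes for phytojip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for phytojip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytojip)
```

phytojip implements the quantitative reductions used when comparing plant
genotypes under abiotic stress: the JIP test on fast chlorophyll *a*
fluorescence transients, 820 nm transmittance (P700) kinetics, agronomic
trait statistics, ddCt expression analysis, and a GC-MS metabolite
statistics chain. This vignette records the models, the defaults and the
reasoning behind the genuinely open design choices, so that results are
interpretable and the package's validation strategy is transparent.

## The JIP test

A dark-adapted leaf exposed to saturating light shows a polyphasic
fluorescence rise between 10 µs and 1 s with inflections labelled O
(origin), J (~2 ms), I (~30 ms) and P (peak). The JIP test reduces this
transient to a handful of biophysically interpretable parameters:

* `Fv/Fm = (Fm − Fo)/Fm` — maximum quantum yield of PSII photochemistry;
  ~0.8 in unstressed leaves.
* `M0 = 4 (F300 − Fo)/(Fm − Fo)` per millisecond — the O→300 µs chord slope
  of the relative variable fluorescence, proportional to the maximum rate
  of Q_A reduction. The factor 4 is 1/0.25 ms.
* `RC/ABS = (1 − Fo/Fm) / [4 (F300 − Fo)/(FJ − Fo)]` — density of active
  PSII reaction centers per absorbed photon flux (inverse antenna size).
* `PI(abs) = RC/ABS · [(Fv/Fm)/(1 − Fv/Fm)] · [(Fm − FJ)/(FJ − Fo)]` — the
  performance index, multiplying reaction-center density, the trapping
  ratio, and the efficiency of electron transfer beyond Q_A.
* `V_t = (F_t − Fo)/(Fm − Fo)` and the double-normalized variants
  `W = (F_t − Fo)/(F_anchor − Fo)` over the O–J, O–I and O–P spans, which
  make phase shapes comparable across samples.
* The area between the Fm level and the curve, raw (fluorescence·s) and
  divided by Fv (the Sm convention, seconds) — proportional to the pool of
  electron acceptors that must be reduced to close all PSII centers.

All ratio parameters are invariant to the instrument gain (multiplying F by
any c > 0); only the raw area scales. The test suite asserts this on
generated curves.

### Marker conventions

Fast fluorimeters log-space their sampling, so markers are read by **linear
interpolation of F against log10(t)**, which preserves curve shape across
decades; the same interpolation is used for resampling when averaging or
differencing transients.

* **Fo read time, 20 µs (default, configurable).** Instruments record from
  10 µs but the earliest samples are the least reliable; 20 µs is the common
  fast-fluorimeter convention for the O level.
* **FJ at exactly 2 ms, FI at 30 ms (defaults, configurable).** The J step
  is conventionally "~2 ms"; we read it at a fixed time rather than
  detecting an inflection, because inflection detection adds estimator
  variance without changing any downstream comparison and is out of scope.
* **Fm = global maximum of the record** (ties broken by the earliest time),
  not F(1 s): under stress the P level can be reached before the end of the
  record.
* **M0 by the chord (default) or a least-squares fit** of V against t over
  50–300 µs (`initial_slope(..., method = "fit")`). Which one an instrument
  reports is vendor-specific, so both are available; the chord is the
  classical printed definition and is what `jip_parameters()` tabulates.
* **Area integrated over linear time** from the Fo read time to t(Fm).
  "Area over the curve" is ambiguous between linear and log time in the
  literature; linear time keeps the closed-form identity with the
  acceptor-pool interpretation (a linear O→P ramp over [t0, t1] gives
  exactly Fv·(t1 − t0)/2) and both raw and Sm-normalized values are
  reported.
* **Degenerate transients** (Fm ≤ Fo) raise a classed error in single-curve
  functions; in `jip_summary()` they become flagged rows excluded from
  group statistics with a reported count, as do curves whose marker ladder
  Fo ≤ F300 ≤ FJ ≤ FI is violated (non-monotone rises happen with damaged
  leaves and should be inspected, not averaged away).

## 820 nm transmittance

P700 oxidation lowers leaf transmittance around 820 nm; re-reduction by
electrons arriving from PSII restores it. Published comparisons are
qualitative — curve overlays and genotype orderings — so the module reduces
each record to the minimal statistics supporting such claims: the
**oxidation amplitude** `1 − min(I/I0)`, the trough time, and the final
recovery level, after normalizing to the first sample. The minimum is
located on the raw sampled grid without interpolation because the signal is
smooth and densely sampled. Normalization is on by default (instrument
gains differ between leaves); raw values can be kept by skipping
`normalize_transmittance()`.

## Trait statistics

Group summaries use mean and `SE = sd/√n`; `percent_reduction(v, r) =
100·(1 − v/r)` is the quantity behind "yield fell by X%" statements, kept
unrounded with integer rounding applied only at the report layer.
Electrolyte leakage follows the EC1/EC2·100 convention of the standard
membrane-injury protocol (initial conductivity of the bathing solution over
conductivity after complete lysis). The two-sample test is the classical
pooled-variance Student *t* (Welch behind `var_equal = FALSE`), and the
post hoc is **Fisher's protected LSD**: pairwise LSD comparisons are made
only when the omnibus one-way ANOVA is significant at the same alpha, which
is what keeps the family-wise null error rate near alpha — the test suite
and acceptance script verify the rate by simulation. ANOVA and the t test
are computed by `stats::aov()`/`stats::t.test()`; the test suite checks
them against an independent brute-force sums-of-squares oracle.

The packaged yield-trait table (`yield_trait_fixture()`) transcribes a
published rice stress experiment's group means and SEs (WT, an
overexpression line OEIF2 and a knock-down line KDIF2 under control,
salinity and heat; n = 9 per cell). Two cells of its panicle counts are
ambiguous in the source's typesetting; they were reconstructed to the
values that make the table internally consistent (panicles × filled
spikelets = total yield, exactly, for all three genotypes under heat) and
consistent with the source's own percent statements. One transcription
(WT salinity total yield = 3) is inconsistent with the product of its
components but is kept as printed; it feeds no reported percentage.

## ddCt expression

`dCt = mean Ct_target − mean Ct_reference` per sample (replicate wells
averaged before differencing — no pairing structure is assumed);
`ddCt = dCt_sample − dCt_calibrator`; `RQ = 2^−ddCt` with amplification
efficiency fixed at 2. RQ is exactly 1 for the calibrator and invariant to
any constant shift of all Ct values. The display transform is
`log10(2^−ddCt)` by default, with base 2 optional; efficiency-corrected
models and multi-reference normalization are out of scope.

## Metabolite statistics

The chain mirrors standard GC-MS practice: divide every sample by its
spiked internal standard (ribitol) to cancel extraction/injection loading;
drop metabolites detected (nonzero) in fewer than half the samples; compute
per-genotype `log2(mean stress / mean control)` per time point on the
normalized linear-scale intensities (means, not medians — the aggregation
is not specified in the conventions this follows, and means match the
generator's ground truth analytically); classify metabolites as up/down by
a sign rule (threshold 0) or a |log2 FC| cutoff, and intersect the two
genotypes' sets per time point (Venn). Undefined ratios (zero or missing
group means) are flagged NA, never zeroed. PCA runs on column-centered,
unit-variance-scaled data by default — scaling is the common choice when
metabolite intensities span decades — via `stats::prcomp()`, with
explained-variance fractions that sum to 1; box–whisker summaries report
mean ± 1.96·sd, an approximate 95% range under normality.

## The synthetic-data generators

Every analysis stage is validated against seeded generators with known
ground truth; they emulate the *structure* of the five input kinds, not the
biology:

* **OJIP**: `F(t) = Fo + (Fm − Fo) Σ w_k / (1 + (τ_k/t)^{h_k})` — a
  weighted sum of three Hill-type sigmoids (defaults Fo = 500, Fm = 2500,
  weights 0.5/0.25/0.25, half-times 0.4 ms/10 ms/100 ms, steepness 2, 118
  log-spaced points over 10 µs–1 s). This reproduces the O-J-I-P geometry
  with V analytically known at any time — e.g. V(2 ms) = 0.490 at the
  defaults — enabling exact recovery oracles. It is **not** a mechanistic
  electron-transport model: no connectivity, no quenching, no I-P
  dissection, so passing recovery tests demonstrates estimator correctness,
  not physiological realism. Note the closed form already sits ~2.5
  fluorescence units above Fo at the 20 µs read time, which bounds how
  exactly Fo itself can be "recovered"; ratio parameters are unaffected.
* **820 nm**: `I/I0 = 1 − A·g(t)/max g` with
  `g = (1 − e^{−t/τ_ox}) e^{−t/τ_red}` (defaults A = 0.05, τ_ox = 0.02 s,
  τ_red = 0.5 s, 120 points over 0–2 s). The oxidation–recovery product is
  scaled by its analytic maximum so the programmed A is the exact realized
  trough depth — without that scaling the realized depth would be ~0.84·A
  at the default time constants and "recovery of A" would be ill-defined.
  Under 0.2% per-point noise, normalizing by the single first sample puts
  an irreducible ~0.003 sd floor on any one record's amplitude error; the
  validation therefore checks that the estimator is unbiased (ensemble mean
  within 0.005 of A over 100 seeds) and bounds individual errors at 0.01.
* **Traits**: replicate values are `mean + N(0, (SE·√n)²)` around the
  packaged yield table (n = 9), so `group_summaries()` recovers the
  configured means/SEs in expectation.
* **Ct**: reference Cts are Gaussian; target Cts are constructed as
  `Ct_ref + dCt_cal − log2(RQ_true) + noise`, making ddCt recovery exact at
  zero noise by construction.
* **Metabolites**: `2^(baseline + effect·[stress]) × loading × (1 + noise)`
  with disjoint programmed up/down sets per genotype and time point and
  the internal-standard column carrying the per-sample loading alone, so
  ribitol normalization removes it exactly.

Noise is multiplicative Gaussian throughout (instrument-like gain noise);
all generators are pure functions of their configuration and seed, and
restore the caller's RNG state.

## Numerical choices and problem sizes

Interpolation is linear in log10 time everywhere; marker reads outside the
sampled range raise a range error rather than extrapolating. Exactly
constant ANOVA inputs are resolved to F = 0, p = 1 (and separated constants
to F = ∞) with a scale-relative guard against floating-point dust from the
model fit. Fold-change entries and PCA inputs never impute: missingness is
flagged or filtered explicitly.

The validation suite sizes were chosen to make the stochastic checks
well-resolved while keeping a full run in tens of seconds: 100 seeds for
OJIP and 820 nm recovery, 50 for ranking and Venn sensitivity, 200 random
instances against the ANOVA oracle, 2000 null replicates for the
protected-LSD family-wise rate and 10000 for the t-test size; smaller
module-level variants of the same checks (20 seeds) run alongside the unit
tests. `scripts/acceptance.R` re-runs the full-scale versions from the
installed package and writes the resulting statistics as JSON.

## Known limitations

* No kinetic modelling of PSII electron transfer, quenching analysis (NPQ,
  qP), spectral corrections, or energy-flux parameters beyond those listed.
* No deconvolution of the 820 nm signal into P700⁺ and plastocyanin
  contributions, and no rate fitting of the recovery phase.
* No mixed models or multiple-testing corrections beyond the protected-LSD
  gate; no primer-efficiency estimation for qPCR.
* The metabolomics chain starts from an intensity matrix: peak detection,
  alignment and identification are upstream instrument-software tasks, and
  supervised methods (PLS-DA) are deliberately not included — the PCA
  covers the unsupervised overview only.
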