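---
title: "Calibrating an ATR infrared assay for bovine serum IgG: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating an ATR infrared assay for bovine serum IgG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atrigg)
```

## The problem

Failure of transfer of passive immunity (FTPI) — a newborn calf's serum IgG
below 1000 mg/dL — is a major risk factor for neonatal disease. The reference
assay, radial immunodiffusion (RID), takes 18–24 hours; attenuated total
reflectance (ATR) mid-infrared spectroscopy of a dried serum film takes
minutes. The catch is that an ATR spectrum is not an IgG measurement: IgG,
albumin and the non-protein residue all absorb in overlapping amide and
fingerprint bands, so a multivariate calibration must be trained against RID
values and then validated as a method-agreement and diagnostic problem.

`atrigg` implements that whole chain: a synthetic generator of replicate
dried-film spectra with known IgG truth, the pre-processing stack
(Savitzky–Golay smoothing/derivatives, SNV and vector normalization, region
selection, a per-wavenumber Dixon Q-test replicate screen), PLS1 calibration
with Monte Carlo cross-validation (MCCV) to pick the number of latent
factors, and the evaluation statistics (Pearson *r*, Lin's concordance
correlation, Bland–Altman limits of agreement, RPD/RER, modified CV*, and
2×2 FTPI diagnostics).

## The simulator: what it emulates and what it does not

Each replicate spectrum follows a Beer–Lambert mixture on a descending
4000–650 cm⁻¹ grid (default 4 cm⁻¹ point spacing, final point clamped to
650):

$$A(\nu) = t \sum_i c_i\, \varepsilon_i(\nu) + b_0 + b_1 \tilde\nu + e(\nu)$$

with three components. IgG's amide I band is placed at 1642 cm⁻¹
(β-sheet-rich immunoglobulin) against albumin's 1656 cm⁻¹ (α-helix), with
amide II near 1550 cm⁻¹ and the broad amide A band at 3300 cm⁻¹; the
non-protein residue contributes weak broad fingerprint bands. That one-band
position shift plus differing relative intensities keeps the components
linearly independent, which is what makes the inverse problem solvable at
all.

Defaults were chosen once, on domain realism:

| parameter | default | why |
|---|---|---|
| samples × replicates | 250 × 5 | the study design the pipeline targets |
| IgG truth | truncated lognormal, meanlog log(1250), sdlog 1, on [5, 3000] mg/dL | right-skewed with ≈51% below 1000 mg/dL, so diagnostic evaluation is non-degenerate |
| albumin, residue | 3.0 ± 0.3, 2.0 ± 0.3 g/dL | bovine serum chemistry |
| detector noise | 0.001 AU | 32 co-added scans |
| film-thickness scatter | lognormal, sd 0.1 | hand-dried films vary ≈10% in effective thickness |
| baseline offset/tilt | 0.001 AU | residual instrument drift |
| diamond-window noise | 0.003 AU, 2200–1900 cm⁻¹ only | internal-reflection-element coating |
| outlier rate | 1% per replicate | occasional failed films |

A gross outlier replicate is the whole spectrum scaled by 1.2 plus an offset
of 10× the noise SD (`inject_gross_outlier()`).

What the simulator does *not* model: evanescent-wave optics and penetration
depth (ATR physics is abstracted into additive band shapes), film-drying
heterogeneity beyond a scalar thickness factor, structured (non-white)
instrument noise, water-vapour/CO₂ lines, and error in the RID reference
values themselves. These omissions matter for interpreting results below:
synthetic performance is *optimistic* relative to the real assay, so passing
tests demonstrate the pipeline's correctness, not field accuracy.

## Pre-processing order and numerical choices

Stages run per replicate, in this order: smoothing **or** derivative →
normalization (on the full 4000–650 cm⁻¹ spectrum) → region selection
(3700–2600 and 1800–1300 cm⁻¹, the strong-absorption windows) → Dixon
replicate screen → averaging of survivors.

* **Savitzky–Golay**: 9-point window, quadratic, coefficients from the local
  least-squares design; ends are mirror-padded so output length equals input
  length. Any polynomial of degree ≤ 2 is reproduced exactly at interior
  points. Derivatives come from the same filter family and are taken with
  respect to *increasing* wavenumber regardless of storage order. The one
  clamped point at 650 cm⁻¹ makes the extreme grid edge slightly non-uniform;
  it lies outside the selected regions, so the approximation is immaterial.
* **Dixon screen**: at every retained wavenumber, the r10 statistic (gap over
  range) is tested at both extremes against the tabulated critical value
  (n = 5, 95%: 0.710; table embedded for n = 3–7 at 90/95/99%). A replicate
  flagged at more than 50% of points is excluded whole; the screen runs once
  (no re-screening of survivors), and at least two replicates must survive.
  Zero-range points flag nobody. Because fractions across replicates sum to
  at most 1, at most one replicate per sample can ever exceed the 50% rule —
  the screen is by construction a *single*-outlier test, and two identical
  anomalies in one group mask each other (a standard Dixon limitation).
* **Screen visibility**: the injected anomaly is affine, and SNV is exactly
  invariant to affine transformations of a spectrum. After SNV the anomaly is
  therefore both invisible *and harmless* — SNV has already repaired it. The
  screen's detection power is consequently demonstrated on smoothed,
  non-normalized spectra with thickness scatter disabled, which isolates what
  the test is for. Under exchangeable white noise the screen flags ≈5% of
  points per sample (split across replicates) and excludes nobody.

## Calibration: PLS1 with Monte Carlo cross-validation

PLS1 is classical NIPALS with deflation of both X and y; X is mean-centred
only (spectra are normalized as spectra — per-wavenumber autoscaling is not
meaningful after SNV). The regression vector is $b = W(P^TW)^{-1}q$; factor
extraction stops early if the residual covariance or score energy falls
below 10⁻²⁴ of the first factor's (a relative criterion, so the
tiny-magnitude second-derivative representations are handled identically to
raw absorbances). At full rank the fit reproduces least-squares predictions;
score vectors are mutually orthogonal; training error is non-increasing in
the factor count.

Factor selection repeats, per Monte Carlo split: draw a random train half
(67 of a 133-sample calibration set), recompute centring on it, fit up to 30
factors, and accumulate squared validation errors;
$\mathrm{RMMCCV}_k = \sqrt{\sum e_k^2 / (R\,n_{val})}$ pooled over repeats.
The chosen factor count is the smallest k attaining the minimum
(parsimony tie-break). The pooled denominator and per-split recentring are
deliberate choices; both are stated here because alternative conventions
(per-repeat averaging, fixed centring) exist and give slightly different
curves. The default is 10,000 repeats; a few hundred already stabilize the
minimum at this problem size, and the bundled tests and acceptance script
run at 200–500 repeats.

The study design around the calibration: samples outside their RID kit's
closed working range (standard 196–2748, ultra-low 10–100 mg/dL) are
excluded first; the retained samples are sorted by reference IgG (ties
broken by sample id) and ranks 1, 4, 7, … form the prediction set — 67 of
200 — which therefore spans the full concentration range and never touches
model selection or fitting. All preprocessing is per-replicate, so no
statistic pools information across samples and the prediction set cannot
leak into the model.

## Evaluation conventions

* Bland–Altman differences are test − reference, limits at mean ± 1.96
  sample SDs.
* Lin's CCC uses population (1/n) moments; |CCC| ≤ |r| always, with equality
  when means and variances agree.
* RPD uses the *population* SD of the reference values, per its standard
  definition; CV and Bland–Altman use sample SDs. Both conventions are
  computed explicitly rather than inherited from whichever function was
  handy.
* CV* = CV(1 + 1/(4n)) is computed from per-replicate predictions of the
  final model (each surviving replicate predicted separately). The RID-side
  CV* is not computable here: the simulator's reference truth is a scalar
  per sample, with no replicate RID wells modelled.
* Negative predicted concentrations (possible near zero for an affine
  calibration) are clamped to zero before FTPI classification; FTPI is
  strictly `IgG < cutoff` with the cut-off at 1000 mg/dL.
* Diagnostic rates with zero denominators are reported as `NA`, never 0.

## What "passing" demonstrates — and two honest limits

**Parameter recovery.** With deterministic film optics (no thickness
scatter, no baseline drift) and 0.001 AU noise, the full pipeline with
smoothing-only preprocessing recovers truth essentially exactly on the
held-out third (r ≈ 0.99999, RMSEP ≈ 0.5% of the truth SD). This is the
regime that validates the linear algebra end to end.

**The SNV ceiling.** Per-spectrum normalization (SNV or vector) divides each
spectrum by a statistic that depends on its own composition. Over a wide IgG
range (5–3000 mg/dL against ~5 g/dL of other solutes) that makes the
normalized spectrum a *curved* function of the concentrations, and no affine
predictor can invert it exactly: with SNV the simulator caps near r ≈ 0.98
even at zero noise. This is not an implementation defect — it is the price
of scatter correction, and it is why the recovery check above uses the
smoothing-only variant while the study-conditions run (scatter on, SNV on)
reports the realistic figures. The real assay's prediction-set r of ~0.93
lives on the same trade-off, compounded by noise sources this simulator
omits.

**Derivatives and noise.** In this generator the noise is white and mild, so
9-point SG derivatives lose almost nothing at default noise — the
second-derivative variant can even win. The classical ordering (smoothing
beats derivatives) emerges robustly once detector noise dominates band
curvature (≥ 0.01 AU here), and that is the regime in which the package
tests assert it. On real instruments, structured noise pushes the crossover
much lower, which is why smoothing won on the bench.

## Problem sizes used by the bundled checks

The test suite and `scripts/acceptance.R` run the full design (250 × 5
spectra) with MCCV at 200–500 repeats, the Dixon screen calibration over 500
replicate groups, and the PLS-vs-least-squares equivalence over 50 random
10×6 problems; one end-to-end study-conditions run takes a few seconds on a
single core. These sizes were chosen as the smallest that make the Monte
Carlo quantities stable to well within the asserted margins.

## Known limitations

* The Dixon screen is a single-outlier test per sample; two simultaneous
  gross outliers mask each other (flagged honestly in the truth table, and
  SNV repairs affine anomalies regardless).
* The kit working ranges and the retained-sample concentration span are
  taken as given, including their mutual inconsistency in the motivating
  study design (retained values below 196 mg/dL under a 196–2748 kit);
  exclusion is range-driven and configurable rather than silently
  reconciled.
* `read_manifest()` requires one shared wavenumber grid; no interpolation
  between grids is attempted.
* No multiplicative scatter correction, rubber-band baseline removal, or
  atmospheric compensation — the pre-processing set is exactly the nine
  compared variants.
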