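---
title: "Quantifying acid 5'-exonuclease activity from fluorescence-quenched oligonucleotide assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying acid 5'-exonuclease activity from fluorescence-quenched oligonucleotide assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efqo)
```

## The assay and its measurement model

The end-labeled fluorescence-quenched oligonucleotide (EFQO) assay measures
acid 5'-exonuclease activity — the activity of lysosomal enzymes of the
phospholipase-D family (PLD3, PLD4) that sequentially release nucleotides
from the 5' end of single-stranded DNA. The substrate is a short ssDNA
oligonucleotide carrying a 5' FAM fluorophore and a 3' quencher: intact
substrate is dark, and release of the terminal fluorophore-coupled 5'
nucleotide separates fluorophore from quencher and produces fluorescence.
A plate reader records each well's fluorescence (excitation 485 nm,
emission 528 nm) every 5 minutes for 12 hours at 37 °C, after a 30-minute
preincubation; `t = 0` throughout this package is the first read after
preincubation.

Raw well intensities contain, besides the product signal, an instrument
background, slow linear drifts (photobleaching of intact substrate,
lysate autofluorescence), and — when quenching is incomplete — a constant
leak from intact substrate. Two control wells run alongside the samples
isolate the drifts: a substrate-only control (no enzyme) and an
enzyme-only control (no substrate). The corrected sample trace is

$$I_C(t) = I_M(t) - I_{M0} - \left(\frac{dI_S}{dt} + \frac{dI_E}{dt}\right) t,$$

where $I_M$ is the measured sample intensity, $I_{M0}$ its value at
$t = 0$, and $dI_S/dt$, $dI_E/dt$ the drift rates of the two controls.
The package estimates the two derivatives as ordinary-least-squares slopes
over the full control traces (`estimate_drift()`), because the controls
are modeled — and in practice observed — as linear in time; the baseline
default is the single $t=0$ read (`estimate_baseline()`, configurable to
average the first $m$ reads when noise warrants it).

Fluorescence is converted to moles through the calibration coefficient
$k$ (AU per mole of hydrolyzed substrate): known substrate amounts are
digested to completion with excess enzyme, each plateau $I_{max}$ is read
off as the signal of a fully digested amount (`estimate_plateau()`, mean
of the last 6 reads by default, with a warning if the trace is still
rising), and $k$ is the slope of the OLS line of $I_{max}$ on moles
(`fit_calibration()`). The intercept is left free and reported rather
than forced through the origin, absorbing residual background-subtraction
imperfections. Activity is then

$$A = \frac{dI_C/dt}{k} \quad [\mathrm{mol/min}],$$

with specific activity $A$ per mg of lysate protein. The derivative
$dI_C/dt$ is realized as an initial-rate window slope — by default OLS
over the first 12 reads (one hour), which is meaningful because assay
conditions keep the substrate in excess; a `max_rolling` policy (steepest
12-read window) is available for traces with a lag phase. Whether the
original analysis used a window or the full curve is not stated anywhere
we could rely on; the windowed initial rate is this package's documented
choice, and all comparative results in the acceptance checks are ratios,
which are insensitive to it.

"Integrated activity" — a per-well scalar used for condition comparisons —
is likewise not given a formula in the source protocol. This package
defines it as the trapezoidal area under $I_C(t)$ divided by $k$
(mol·min, `compute_activity()$integrated_activity`). This is an
interpretation, flagged as such; conclusions drawn from it in this
package are again ratio-based.

Negative corrected slopes (e.g. knockout lysates) are reported as-is with
a `below_detection` flag rather than truncated at zero, so that
below-detection-limit wells remain visible in downstream tables.

## The progress-curve simulator

Every stage of the pipeline is validated against a forward simulator
(`simulate_trace()`, `simulate_plate()`) whose defaults are the standard
assay conditions: 1 µM substrate in 100 µl, 5 ng/µl protein (0.5 µg per
well), 5-min reads for 720 min, 30-min preincubation, 37 °C.

Substrate decay follows single-substrate irreversible Michaelis–Menten
kinetics with no product inhibition — the simplest model consistent with
the observed saturating, complete hydrolysis — via the closed form
$S(t) = K_m W_0[(S_0/K_m)\,e^{(S_0 - V_{max} t)/K_m}]$
(`integrated_mm_substrate()`; the Lambert-W evaluation is an in-package
guarded Newton iteration, with a bracketed root solve of the conservation
relation $K_m\ln(S_0/S) + (S_0 - S) = V_{max}t$ as fallback, and is
tested against adaptive ODE integration to a relative tolerance of 1e-6).

The measured sample intensity is assembled as
$$I(t) = bg + (1-q)\,k\,S(t)\,V + k\,(S_0 - S(t))\,V + (a_S + a_E)\,t + \varepsilon(t),$$
with $q$ the quench efficiency, $k$ the generative fluorescence
coefficient, $V$ the volume, $a_S, a_E$ the control drift slopes and
$\varepsilon$ i.i.d. Gaussian read noise. The substrate-only control
carries $bg + (1-q)kS_0V + a_S t$, the enzyme-only control $bg + a_E t$.
By default the sample well's drift is exactly $a_S + a_E$
(`sample_drift_policy = "sum_of_controls"`), the generative assumption
under which the control-based correction is unbiased; a `custom` policy
exists to study robustness to drift mismatch. Under that default, with
$q = 1$ and no noise, the correction recovers
$I_C(t) = k(S_0 - S(t))V$ to machine precision — the simulator and the
correction formula are exact inverses, which is the package's central
self-consistency test.

Condition effects enter as one multiplicative factor on $V_{max}$
(`modifier_factor()`): a logistic inhibitor term $1/(1+(c/IC_{50})^h)$
(or a fixed inhibition fraction), an activation factor (chelators such as
EDTA act here), a Gaussian pH bell
$\exp(-(pH-pH_{opt})^2/2w_{pH}^2)$ and a descending thermal logistic
$1/(1+e^{(T-T_m)/w_T})$, times the substrate's phosphorothioate (PTO) and
terminal-5'-base rate factors. The Gaussian and logistic shapes are
implementation choices — the underlying profiles are published as plots
without functional forms — chosen for identifiability with few points;
the profile estimators fit the same families, so shape misspecification
is deliberately not exercised by the recovery tests.

### Default parameter choices

| parameter | default | rationale |
|---|---|---|
| $S_0$ | 1e-6 mol/L | standard assay concentration |
| volume | 1e-4 L | 100-µl reactions |
| $K_m$ | 5e-6 mol/L | not published; places $S_0 < K_m$ so dose series saturate realistically |
| $V_{max}$ | 2e-9 mol/(L·min) | with $K_m$ above, the default 12-read window consumes ~2% of substrate — the substrate-excess regime the assay is run in |
| $k_{AU}$ | 1e13 AU/mol | gives a 1000-AU full-digestion plateau for 0.1 nmol, a realistic reader scale |
| quench efficiency $q$ | 0.95 | quenching is good but not perfect; the leak appears as constant background and cancels in the correction; the fitted calibration slope becomes $q\,k_{AU}$, so activities are unaffected |
| background | 50 AU | typical reader offset |
| drifts $a_S, a_E$ | 0.05, 0.02 AU/min | small linear drifts (≤5% of plateau over 12 h) |
| noise sd | 2 AU | ~0.2% of plateau per read; no noise characterization is published, so additive i.i.d. Gaussian is the simplest seedable choice |
| protein | 5e-4 mg/well | 5 ng/µl × 100 µl |
| 5'-base factors | T 1.0 > A 0.8 > G 0.55 > C 0.35 | only the qualitative order is established; values are generator conventions |

The default substrate is the standard 30-mer with its three 3'-terminal
PTO linkages stored explicitly (indices 26–28, 0-based); the published
description is ambiguous between three and four PTO linkages, so the
constructor records whatever set it is given and never infers one.

Noise is reproducible: each well draws from a seed derived
deterministically from the plate's master seed and the well position, and
the generator restores the caller's RNG state.

What the simulator does *not* emulate: sequence-resolved stepping of the
exonuclease along the oligonucleotide (only terminal-release fluorescence
is modeled), secondary structure of unusual substrates, product
inhibition, evaporation or edge effects, and non-Gaussian reader noise.
Passing recovery tests therefore demonstrate correctness of the analysis
chain under the stated generative model, not robustness to every artifact
of real plates.

## Downstream fits

All nonlinear fits use Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) with fixed, deterministic initializations — no
random restarts — so results are exactly reproducible:

* `fit_mm()`: $v = V_{max}S/(K_m+S)$, initialized at the maximal observed
  rate and the interpolated half-maximal concentration; requires ≥4
  distinct concentrations spanning ≥4-fold.
* `fit_4pl()`: four-parameter logistic in log dose with free Hill slope
  bounded to [0.2, 5] (the published IC50 analysis does not state whether
  the Hill slope was free, so it is left free but bounded for
  identifiability). Zero-dose anchors are placed two decades below the
  smallest nonzero dose on the log axis and recorded in the fit object.
  A flat response raises an undefined-IC50 error instead of returning an
  arbitrary number.
* `estimate_ph_optimum()` / `estimate_thermal_midpoint()`: Gaussian bell
  and descending logistic, with an argmax fallback when the fit fails and
  a boundary flag when the profile does not peak (or decline to half-max)
  within the sampled range; reported optima are clamped to that range.
  The thermal initialization interpolates the half-max crossing, so a
  step-like profile returns the midpoint of the step interval rather than
  an arbitrary point inside it.

Fits are checked two ways: exact recovery of generative parameters on
noise-free data, and dense grid searches over the nonlinear parameters
(with linear parameters profiled out) confirming the optimizer attains
the global least-squares optimum.

## Group statistics

Replicates are summarized as mean ± SEM ($sd/\sqrt{n}$; SEM omitted for
$n = 1$). Fold changes between conditions are ratios of group means with
seeded bootstrap percentile confidence intervals (2000 resamples by
default). Many-to-one comparisons use Dunnett's procedure on the pooled
one-way-ANOVA variance: the adjusted p-value
$P(\max_j |T_j| \ge |t_i|)$ is computed under the equicorrelated
multivariate-t distribution by deterministic Gauss–Hermite ×
Gauss–Legendre quadrature (80 × 96 nodes; absolute error well below
1e-6), not by Monte-Carlo sampling, so p-values are bit-reproducible and
the $k=1$ case agrees with the two-sample pooled t-test to numerical
precision. Homogeneous within-group variance is assumed, as in the
standard procedure. Significance stars follow the four-tier scheme
0.05 / 0.01 / 0.001 / 0.0001. Substrate-preference rankings
(`rank_preference()`) order variants by mean activity and flag — rather
than arbitrarily break — ties whose mean ± SEM intervals overlap.

## Numerical choices and degenerate inputs

* Progress-curve evaluation validates the conservation relation at every
  point and raises an explicit error rather than returning silent NaNs;
  numerically exhausted substrate (below $10^{-12} S_0$) is clamped to 0.
* `initial_rate()` needs ≥4 points; a window longer than the trace
  shrinks to the full trace with a warning.
* Calibration requires ≥2 distinct amounts and a positive slope
  (an inverted dilution series is an invalid-calibration error).
* Plateau estimation warns when the tail slope exceeds 5% of the trace's
  steepest rolling slope (digestion incomplete).
* All traces in a plate must share one time grid; resampling is out of
  scope and a mismatch is an error, not a silent interpolation.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on simulated
plates: single wells plus two controls for the exact-inverse identities,
a 4-point dilution series for calibration, 8-dose inhibition series,
9-point pH and 14-point temperature profiles, triplicate two-enzyme
plates for the fold-change comparison, and a 2000-replicate null
simulation (4 groups × 5 observations) for the Dunnett family-wise error
rate. These sizes mirror the corresponding bench experiments while
keeping the full suite fast on a single CPU.

## Known limitations

* Absolute molar activities require a calibration ($k$); without one,
  only fluorescence-rate comparisons are possible.
* The correction assumes sample-well drift equals the sum of the control
  drifts; plates violating this (e.g. strongly lysate-dependent
  photobleaching) bias absolute activities, though ratio comparisons are
  less sensitive.
* Mechanistic inhibition modeling (competitive vs noncompetitive), plate
  or batch random effects, and power analysis are out of scope.
* The pH and thermal profile forms are phenomenological; fitted optima
  and midpoints should be read as curve summaries, not thermodynamic
  constants.
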