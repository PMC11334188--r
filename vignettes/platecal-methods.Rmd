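---
title: "Methods: dilution-scheme metrology with platecal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dilution-scheme metrology with platecal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platecal)
```

## Problem

Automated liquid handlers fill 96-well plates by sequences of aspirate and
dispense steps. Every step carries error — independent volume noise,
systematic gains, droplet contamination, and, in serial (column-to-column)
dilutions, carryover that compounds down the series. When such plates feed a
calibration curve, those errors propagate into every downstream
quantification. `platecal` packages the full loop needed to study this:
design the plates, simulate their execution under explicit error models,
and run the analytics that detect, quantify, and suppress the errors.

## Dilution schemes

Two built-in 96-well layouts cover the two standard dilution idioms. Both
devote columns 1–10 to 80 sample wells, columns 11–12 to 16 blanks (pure
diluent, the zero-concentration reference), and fill every well to 200 µL.

* **Linear (direct) scheme** — every well is filled straight from a solute
  and a solvent reservoir. Two identical blocks (columns 1–5 and 6–10) each
  hold the 20 ratios $1.00, 0.95, \dots, 0.05$, descending top-to-bottom in
  column-major order with technical repeats every other row (A=B, C=D, E=F,
  G=H). With a 5 % step on 200 µL, every transfer is a multiple of the 10 µL
  safe volume. Errors here are independent per well.
* **Geometric (serial) scheme** — column 1 is filled directly at fractions
  1, 7/8, 3/4, 5/8 of the stock (duplicated row pairs); each later column
  receives a fixed transfer from its predecessor, halving the concentration
  (1:2 fold). The mechanics are fixed as: prefill columns 2–10 with
  $V_p = 200$ µL solvent, fill column 1 to $V_p + V_t$, transfer
  $V_t = V_p/(\mathrm{fold}-1)$ column-to-column with in-well mixing, and
  discard $V_t$ from column 10. Errors in the transfer compound down the
  series — the reason this scheme needs column-stratified analytics.

An ideal execution of either instruction list reproduces the target ratios
exactly (the test suite asserts $\le 10^{-12}$ on all 96 wells).

## Error simulator

`execute_instructions()` does exact bookkeeping of solute mass and total
volume per well. Each transfer volume $v$ becomes
$g \cdot v + \mathcal{N}(0, (\mathrm{cv}\,v)^2) + \mathrm{offset}$, clipped
at zero, with an extra `carryover_excess` on column transfers, an optional
solute-only gain, reservoir concentration error, and contamination droplets
landing in uniformly chosen wells. All parameters default to "off": the
default configuration is the ideal executor. The non-zero magnitudes used in
examples and tests (volume CV 1 %, OD noise 0.002, carryover 30 µL) are
order-of-magnitude placeholders — vendors state only "a few microliters" —
and are deliberately labelled as such; they are *not* measured platform
constants.

`render_absorbance()` turns compositions into wells × wavelengths plates on
the 350–650 nm grid with 2 nm steps:
$$A_i(\lambda) = g(c_i)\, S(\lambda)\, e_i + B(\lambda) + \varepsilon,$$
with $g(c) = c/(1+\gamma c)$ ($\gamma = 0$ recovers Beer–Lambert
linearity; either sign of $\gamma$ is allowed — the analytics, not the
chemistry, are the point of the simulator). The default solute spectrum is
a carotenoid-like triplet of Gaussians at 458, 488, 524 nm (heights 0.70,
0.95, 1.00 OD, width 10 nm — peak half-widths of roughly 25 nm, as typical
for carotenoid vibronic bands). `aging_flatness` mixes the triplet toward a
smooth monotone scattering-like decay: a peak-free limit at 1, emulating
aged mixes whose distinctive peaks disappear through aggregation. We chose
a monotone background rather than a broad Gaussian so that the fully aged
spectrum genuinely contains no local maxima.

Per-repeat transient excursions (solubility events) trigger with
probability proportional to a well's concentration, multiply the solute
signal by $1 + m$ with random sign and scale, and decay geometrically
across repeats while remaining free to re-trigger — giving the
"deviate-then-return-to-trend" trajectories that repeat filtration targets.

What the generator does **not** emulate: viscosity-dependent aspiration,
evaporation, temperature, instrument-specific export dialects, or real
aggregation kinetics. A passing test therefore shows the analytics behave
correctly under the stated error classes — not that any specific hardware
behaves like the simulator.

## Spectrum model

`fit_spectrum_model()` decomposes a plate as
$M_{i\lambda} \approx \alpha_i S_\lambda + B_\lambda$ with everything
nonnegative, minimising
$$\sum_{i\lambda}(M_{i\lambda}-\alpha_i S_\lambda - B_\lambda)^2
  + w \sum_\lambda (B_\lambda - \bar m_\lambda)^2,$$
where $\bar m$ is the blank-well mean. The quadratic penalty (default
$w = 1$) keeps every subproblem closed-form: alternating exact per-well,
per-wavelength clipped least-squares updates make the objective provably
nonincreasing (asserted on the trace). Convergence is relative change
$< 10^{-8}$ or 500 cycles. The $(S, \alpha)$ scale ambiguity is resolved by
normalising $S$ to 1 at a reference wavelength (default: its maximum;
settable to e.g. 400 nm or the 524 nm peak) and rescaling $\alpha$
compensatingly. Initialisation: $B$ from the blank mean, $S$ from the
blank-subtracted strongest well, $\alpha$ by one least-squares pass — a
near-feasible warm start that converges in one cycle on noiseless data.
Zero-variance wavelengths get no special casing; the clipped update handles
them. The fit is checked against a brute-force box-constrained optimizer
(multi-start L-BFGS-B over the full parameter vector) on a small toy
instance.

## Error assessment

The three-step workflow: (1) regress the response (absorbance at a chosen
wavelength, or the $\alpha_i$) on the targeted ratios — OLS with classical
intervals, or Huber IRLS (tuning constant 1.345, MAD scale, via `MASS::rlm`)
when outliers are expected; (2) invert the model per well (degree 1
analytically; degree 2 by selecting the real root on the monotone branch
covering $[0, x_{\max}]$, refusing non-monotone fits; estimates outside
$[-0.1,\, 1.1\,x_{\max}]$ are flagged, never clipped); (3) map residuals and
relative errors (residual / target, samples only) onto the plate. Global
metrics — Pearson, Spearman, RMSE — are computed on (estimated, targeted)
pairs by default; response-based correlations are also reported since
either convention appears in practice. RMSE is on the *ratio scale*
(estimated vs targeted dilution ratios), stated explicitly because the
scale is easy to misread.

Two points deserve emphasis:

* **Internal metrics are blind to uniform biases.** A plate-internal fit
  absorbs a systematic +5 % solute gain completely. Quantifying such a bias
  requires an external reference calibration (`model =` argument); the
  per-well mass-balance inversion
  $g = \hat r (1-r) / (r (1-\hat r))$ implemented in
  `estimate_transfer_gain()` then recovers the injected transfer gain
  exactly in expectation. Note the realized *ratio* bias is not uniform:
  $r' = g r/(gr + 1 - r)$, i.e. +5 % at the bottom of the range decaying
  to 0 at $r = 1$, averaging ≈ +2.3 % across the linear plate.
* **Jump detection needs a bias-free noise scale.** A constant carryover
  compounds smoothly, so the global fit partially tracks it and its
  residual scale grows with the bias — a prediction band built from that
  scale can never expose it (the fraction of points outside is invariant
  to the carryover magnitude). `stratified_trends()` therefore estimates
  the band's noise scale from *pure error*: the within-replicate-group
  scatter afforded by the duplicated rows, the classic lack-of-fit
  decomposition. A stratum is flagged when more than 50 % of its points
  (threshold exposed) leave the 95 % band. With this band, 30 µL carryover
  is detected in every seeded run while clean plates flag nothing; without
  replicates the band falls back to the regression scale and power drops
  accordingly.

`correlation_scan()` reports Pearson, Spearman and tie-corrected Kendall
τ-b per wavelength; a phi-k metric is an optional hook that is not enabled
in this build (requesting it logs a note and omits the column).

## Repeat filtration and calibration

For $R$ technical repeats, `repeat_filtration()` fits one robust trendline
on all pooled (target, value) pairs and keeps, per well, the repeat value
deviating least from it (ties to the lowest repeat index). The selection is
a per-well minimum, so the filtered plate's RMSE-to-trend is bounded by
every single repeat's — an exact property the tests assert on arbitrary
random inputs. The default is a single pass; refit-and-reselect iteration
(at most 10 passes) is opt-in, since a single fit on pooled data is the
simplest faithful version of the procedure. The trendline is fitted per
run, and filtration never invents values — every selected value appears
verbatim in some repeat. Under symmetric, excursion-free noise, filtration
and per-well medians agree to within Monte-Carlo error; its advantage
appears exactly when transient excursions are present.

`combine_runs()` converts ratios to absolute concentrations through
per-run metadata ($C_0$ × working-mix factor × ratio; e.g. a 0.5 mg/mL
stock diluted 4/100 puts a ratio-0.5 well at 0.01 mg/mL), and
`build_calibration()` fits the final robust degree-1 or degree-2 curve
$\mathrm{OD}_\lambda = f(\text{mg/mL})$, reporting $a, b, c$ with
Pearson/Spearman/RMSE of inverted versus nominal concentrations.

`aggregate_spectrum()` averages normalized spectra and reports peaks by
topographic prominence (default 5 % of the maximum, ≥ 10 nm apart —
resolving the 458/488/524 nm triplet at 2 nm sampling without reporting
noise wiggles). `spectral_drift()` gives the minimal stability summary:
per-timepoint Pearson similarity to $t = 0$ and retention of the main peak.

## Problem sizes and reproducibility

All Monte-Carlo statements in the tests and in `scripts/acceptance.R` use
20 seeded replicate simulations of full 96-well plates (10 technical
repeats for the filtration studies) — enough to make the majority-vote and
±1-percentage-point claims stable across seeds while keeping the whole
suite inside a few seconds on one CPU. Every stochastic stage takes an
explicit integer seed; identical seed and configuration give bit-identical
output.

## Limitations

Single-solute decomposition only; no uncertainty quantification on $S$ and
$B$; no between-plate meta-analysis (the per-plate scale is deliberate);
consistency metrics cannot detect biases that affect all wells equally
unless an external reference model is supplied; and the simulator's error
magnitudes are placeholders, not platform measurements.
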