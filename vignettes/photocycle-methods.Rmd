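---
title: "Methods: spectral unmixing and kinetics of photocyclic pigments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral unmixing and kinetics of photocyclic pigments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photocycler)
```

## The problem

A monostable visual pigment such as vertebrate rhodopsin is spent after one
photon: its active intermediate, metarhodopsin II (meta II, λmax ≈ 380 nm,
unprotonated Schiff base), decays to meta III (≈ 470 nm, all-trans-15-syn
retinal) and eventually releases its chromophore. A *photocyclic* pigment
instead returns thermally from meta II to the original 11-cis dark state, and
a *photoreversible* one can be driven back by UV light. Distinguishing these
behaviours from UV-Vis data requires three quantitative steps, which this
package implements:

1. modelling each state's absorbance shape from its λmax alone (templates);
2. decomposing measured spectra — in particular UV-minus-yellow difference
   spectra — into non-negative state fractions (unmixing);
3. fitting the thermal recovery kinetics and accounting for the retinal
   isomers each state carries.

Because each stage is an inverse problem, the package ships a forward
generator with known ground truth, and every estimator is validated by
recovering what the generator put in.

## Templates

The absorbance shape of an A1 (retinal) pigment is taken from the standard
λmax-parameterised nomogram: an α band

$$S(x) = \frac{1}{e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D}, \qquad
  x = \lambda_{max}/\lambda,$$

with $A=69.7$, $B=28$, $C=-14.9$, $D=0.674$, $b=0.922$, $c=1.104$ and
$a = 0.8795 + 0.0459\,e^{-(\lambda_{max}-300)^2/11940}$, plus a Gaussian β
band of amplitude 0.26 peaking at $189 + 0.315\,\lambda_{max}$ nm. All
constants live in `nomogram_constants()` and can be swapped for an
alternative template family. Evaluation is pointwise on the requested grid
(default 250–700 nm at 1 nm) and the curve is then peak-normalised to 1, so
a state's coefficient in a fit is directly its absorbance contribution at
its own peak.

Per-state choices: meta II is modelled at 380 nm *without* a β band (its α
band already sits in the UV, and a β band there would collide with the
protein region); the dark state and meta III (470 nm) include the β band;
meta I (478 nm) is available as an optional fourth basis member for mutants
that accumulate it, but is off by default because adding a basis member
whose λmax nearly coincides with the dark state degrades the conditioning
of every fit. Whether the original template method used nomogram curves or
empirically measured intermediate spectra is not recoverable from published
material; treating all states as nomogram curves with configurable λmax is
this package's design choice, and the λmax values are explicit arguments
everywhere.

## Spectrum arithmetic

Difference spectra require *identical* wavelength grids; the only sanctioned
alignment is an explicit `resample()` (linear interpolation, no
extrapolation). Silent interpolation inside a subtraction is refused because
it hides grid mismatches exactly where they do the most damage.

λmax is estimated by parabolic (3-point quadratic) interpolation around the
windowed maximum, with a default 420–600 nm window that excludes the meta II
UV band and the protein band. The estimator is exact on a parabola and
invariant to positive scaling and constant offsets. At 0.5% peak-relative
noise on a 1-nm grid the estimate is unbiased well within 1 nm, but its
seed-to-seed SD is ≈ 2 nm — the discrete argmax itself carries that much
jitter on a broad peak, and a 3-point refinement cannot remove it. Means
over seeds, not single-seed values, are therefore the quantity the package
reports for noisy λmax work.

An optional constant-baseline correction subtracts the mean over a stated
flat region (default 680–700 nm). No scattering (1/λ⁴) correction is applied
by default; the generator does not emulate scattering either, so passing
tests say nothing about scattering robustness on real data.

## Unmixing

`fit_components()` solves a plain non-negative least-squares (NNLS) problem
on the template basis. `fit_photoconversion()` implements the model behind a
component-ratio table: the UV-minus-yellow difference spectrum is

$$\Delta A(\lambda) = s \sum_{k \ne \mathrm{ref}} f_k\,
  (T_k(\lambda) - T_{\mathrm{ref}}(\lambda)),
  \qquad f_k \ge 0,\ \sum_k f_k \le 1,$$

with meta II as the reference (photolysed) pool. The inequality is recast
exactly as an equality with a non-negative slack variable and solved by
active-set NNLS; the remainder $1-\sum f_k$ is reported as the reference
fraction, so compositions sum to 100% by construction. The constraint set is
a design decision — the source tables sum to 100%, so fractions are treated
as state populations rather than free regression coefficients.

Two numerical policies matter here:

* **Scale.** A difference spectrum determines only $s f_k$ products. The
  total pigment scale $s$ must come from the pre-irradiation dark-state
  spectrum (absorbance at λmax over the template peak of 1); fitting without
  it is refused rather than guessed.
* **Collinearity.** Two templates at the same λmax make the basis rank
  deficient; the fit errors out rather than regularising, because a
  regularised split between indistinguishable states would be arbitrary.

The fit window defaults to 330–650 nm: wide enough to see the meta II UV
band and the visible bands, short of the protein band. The published fits'
exact window is unstated; this default is declared, not inferred.
Uncertainty comes from a residual-resampling bootstrap
(`bootstrap_fractions()`), seeded and deterministic.

The NNLS solution is cross-checked in the tests against a dense 0.005-step
grid search over the constrained simplex — an oracle that shares no code
with the active-set path.

## Kinetics

The photocycle is a linear first-order network. Within any constant-
coefficient segment (darkness, or continuous light, which adds
intensity-scaled pseudo-first-order excitation rates) populations are
propagated with the matrix exponential of the rate matrix, which conserves
the population sum to 1e−9 and keeps populations non-negative. Flashes are
instantaneous: a stated fraction of each photosensitive state moves along
the band's branching fractions. UV photoreversion branching (meta II →
dark vs meta III) is configurable per pigment, since the printed
compositions imply different splits for wild-type-like and photocyclic
pigments. Meta III is terminal by default — its slow decay is not
quantified on the timescales modelled here.

Thermal recovery traces are fit with
$y(t) = y_0 + A(1 - e^{-t/\tau})$ (rising) or $y_0 + Ae^{-t/\tau}$
(decaying) by Levenberg–Marquardt (`minpack.lm`), with $\tau_0$ initialised
from the time the trace crosses $1-e^{-1}$ of its span and $\tau$ bounded to
$[10^{-3}, 10^6]$ s. Both forms are provided because published fits do not
state their parameterisation; the rising form matches a recovery plotted as
difference absorbance at λmax. The propagator is cross-checked against
fixed-step forward Euler evaluated as $(I + \Delta t\,Q)^{2^k}p_0$ by
repeated squaring, which makes $\Delta t \sim 10^{-6}$ s affordable and an
agreement bound of $10^{-6}$ meaningful.

## Isomer accounting

States map to chromophore configurations (dark → 11-cis-15-anti; meta I and
meta II → all-trans-15-anti; meta III → all-trans-15-syn), making isomer
percentages linear in populations and conserving the 100% total at every
time point. The spectral dark fraction and the 11-cis percentage of the same
sample must agree; `consistency_check()` reports their discrepancy in
percentage points (default pass threshold 3 points). HPLC counting noise is
emulated as multinomial sampling with a user-set effective molecule count.
For regeneration experiments from all-trans retinal the dark pool can be
split 11-cis/9-cis by an explicit, user-supplied share — no default is
assumed because that split is sample-specific.

## Synthetic data and what it does (not) show

`scenario_suite()` ships seven scenarios spanning the modelled experiments:
meta II → meta III decay of a wild-type-like pigment, thermal recovery of a
photocyclic mutant at 20 °C and 37 °C (τ = 57.4 s), UV photoreversal of
both pigment classes with printed-composition branching, and a fast-cycling
double mutant near 0 °C and at 37 °C (τ = 5.1 s). Observation grids mirror
the corresponding experimental sampling (minutes-scale series for 20 °C,
0.1–1000 s and 0.1–50 s for the 37 °C recoveries). Defaults: peak scale
0.05 AU (typical purified pigment), Gaussian noise SD 1% of peak. Neither
the true instrument noise nor flash conversion fractions are published;
these are declared generator parameters, not facts. Each scenario draws
from a stream derived from (master seed, scenario name), so adding
scenarios never shifts existing ones, and `make_fixture_suite()` trees are
byte-identical per seed.

The generator emulates additive Gaussian noise on template-exact spectra.
It does **not** emulate lamp flicker, scattering baselines, temperature
drift, photoproduct heterogeneity, or λmax misspecification; passing
closure tests therefore demonstrates correctness of the estimators under
the stated model, not robustness to every instrumental artefact.

## Problem sizes

The validation suite uses desk-scale problems: 50 seeds per unmixing
recovery (451-point spectra, 3-state basis), 100 seeds per time-constant
recovery (5–7 time points each), 200 seeds per λmax recovery, 20 random
problems per oracle cross-check, and the seven-scenario fixture suite at
1% noise. These sizes give Monte-Carlo means and medians stable to well
inside the tolerances they are compared against.

## Known limitations

* Templates are A1-only; A2 pigments, temperature and pH dependence of
  band shapes, and the 280-nm protein band are out of scope.
* No global (multi-spectrum, shared-kinetics) fitting or SVD of
  time-resolved matrices; each spectrum or trace is fit on its own.
* Rates are per-condition inputs; no Arrhenius extrapolation across
  temperatures.
* G-protein signalling is represented only by the meta II population as an
  "active fraction" proxy; no receptor–G-protein biochemistry is modelled.
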