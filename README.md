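# photocycler

Spectral and kinetic analysis of **photocyclic visual pigments** — opsins
whose light-activated state returns thermally to the original dark state
instead of being stranded in a late photoproduct. The package targets the
UV-Vis workflow used to characterise such pigments (e.g. a rhodopsin G188C
mutant): nomogram template spectra, decomposition of UV-induced difference
spectra into photointermediate fractions, photocycle kinetic simulation,
single-exponential recovery fitting, and retinal isomer accounting. A
seeded synthetic-data generator emulates every experiment so all stages
can be validated against known ground truth at desk scale.

It is written for spectroscopists and photoreceptor biophysicists who
need a reproducible route from raw absorption spectra to component-ratio
tables and recovery time constants.

## The models at the core

**Templates.** A pigment state's absorbance shape is the standard A1
visual-pigment nomogram, parameterised only by its λmax:

    S(x) = 1 / (exp[A(a − x)] + exp[B(b − x)] + exp[C(c − x)] + D),
    x = λmax/λ,  a = 0.8795 + 0.0459·exp(−(λmax − 300)²/11940),

with A = 69.7, B = 28, C = −14.9, D = 0.674, b = 0.922, c = 1.104, plus a
Gaussian β band. Templates are built for the dark state (λmax per
pigment), meta II (380 nm, unprotonated Schiff base; no β band) and
meta III (470 nm), peak-normalised to 1.

**Unmixing.** A UV-minus-yellow difference spectrum is modelled as
photoconversion out of the photolysed meta II pool,

    ΔA(λ) = s · Σ_{k≠metaII} f_k (T_k(λ) − T_metaII(λ)),
    f_k ≥ 0,  Σ f_k ≤ 1,

solved by non-negative least squares over 330–650 nm; the remainder
1 − Σ f_k stays in meta II, so the reported composition sums to 100%.
The total pigment scale `s` is read off the pre-irradiation dark-state
spectrum and never guessed from the difference spectrum.

**Kinetics.** States evolve as a linear first-order network; constant-
coefficient segments are propagated with the matrix exponential, flashes
are instantaneous population moves along per-band branching fractions.
Thermal recovery traces are fit with
`y(t) = y₀ + A(1 − exp(−t/τ))` by Levenberg–Marquardt.

**Isomers.** Populations map to retinal isomers (dark → 11-cis-15-anti,
meta II → all-trans-15-anti, meta III → all-trans-15-syn), so the
spectrally fitted dark fraction can be checked against HPLC-style 11-cis
percentages.

## Worked example

Recover the post-UV composition of a mutant pigment (dark λmax 494 nm)
from a noisy synthetic difference spectrum:

```r
library(photocycler)

tpl   <- build_template_set(c(dark = 494, metaII = 380, metaIII = 470))
truth <- c(dark = 0.181, metaII = 0.517, metaIII = 0.302)
scale <- 0.05  # dark-state peak absorbance, AU

set.seed(1)
obs <- populations_to_spectrum(truth, tpl, scale)          # post-UV mixture
obs$absorbance <- obs$absorbance + rnorm(451, sd = 0.01 * scale)
ref <- template_as_spectrum(tpl, "metaII")                 # post-yellow pool
ref$absorbance <- ref$absorbance * scale

est <- fit_photoconversion(difference_spectrum(obs, ref), tpl, scale = scale)
round(100 * est$fractions, 1)
#>    dark  metaII metaIII
#>    18.2    51.6    30.1
```

The fit returns 18.2 / 51.6 / 30.1% against the generating
18.1 / 51.7 / 30.2% — within the ±2-point band expected at 1% noise. The
same pattern holds for kinetics:

```r
tr <- generate_recovery_trace(tau = 57.4, amplitude = 0.045, offset = 0,
                              times = c(0.1, 1, 10, 50, 100, 500, 1000),
                              sigma_rel = 0.02, seed = 5)
fit_single_exponential(tr$trace)$tau
#> [1] 54.65188
```

a single-seed estimate of the 57.4 s generating time constant (the median
over 100 seeds is within 1%).

The numbered scripts under `analysis/` run the full study-shaped
workflow — templates, photocyclic-vs-monostable simulation, component
unmixing with bootstrap intervals, recovery-kinetics fitting, and isomer
accounting — and write their tables under `results/`.

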