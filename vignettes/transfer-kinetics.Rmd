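---
title: "Measuring sub-hertz proton-carbon couplings from spin-order-transfer kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sub-hertz proton-carbon couplings from spin-order-transfer kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical problem

High-field SABRE starts from parahydrogen adding to an iridium catalyst,
leaving the two chemically inequivalent hydride protons (Hᵃ, Hᵇ) in
longitudinal two-spin order, `Iz(a)Iz(b)`. Transferring that order to a
¹³C spin of a bound pyruvate requires pulse sequences whose efficiency is
governed by scalar couplings of well under a hertz, while the complexes
carrying those couplings live for fractions of a second before ligand
exchange destroys the coherence. Neither the couplings nor the lifetimes
are readable from ordinary spectra: the couplings are buried under
exchange broadening, and the exchange rate is entangled with relaxation.

The package's strategy is the one that works experimentally: drive the
transfer with a frequency-selective sequence whose amplitude is an exact,
closed-form function of one proton-proton and one proton-carbon coupling,
scan a sequence delay, and fit the resulting kinetics.

## The transfer sequence and its amplitude law

`sepp_spinept()` implements the selective transfer chain

```
90°(S) — τ₁—180°(I,S)—τ₁ — τ₂—180°(S,F)—τ₂ — 90°(S), 90°(F)
```

on a spin system of two hydride protons (I, S) and one carbon (F). Each
echo refocuses chemical-shift offsets and all couplings to spins outside
the pulsed pair, while the pair's own coupling evolves for the full `2τ`.
The observable outcome is the carbon antiphase term `2 Sz Fy` with
coefficient

```
a(τ₁, τ₂) = sin(2π J_IS τ₁) · sin(2π J_SF τ₂) · exp(−2 τ₂ R),
```

normalized to the initial two-spin order. This law is the package's
master oracle: the density-matrix simulation reproduces it to 1e−8 over
random couplings and delay grids (tested), so every downstream stage can
treat it as exact. Three structural properties matter for analysis:

* the amplitude is odd in both couplings, so only magnitudes are
  measurable;
* with `τ₁` fixed near `1/(4 J_IS)` the `τ₂` kinetics depend on a single
  unknown coupling;
* exchange and relaxation enter only through the uniform decay
  `R = k_d + R₂` applied during the variable delay. Losses during the
  fixed `τ₁` block rescale the amplitude and are absorbed by the fitted
  `A` (a flag enables damping in both blocks for sensitivity studies).

The simulator treats selective pulses as ideal zero-duration rotations
restricted to their targets; the nominal 10 ms duration is kept only to
warn when two same-isotope spins sit within `2/Δ` of each other, where
ideal selectivity is a fiction. The rotation convention is fixed as
`90°x: Iz → −Iy`, making every sign in the package reproducible.

Weak-coupling (Iz Iz) Hamiltonians are the default for sequence
execution: for the hydride pairs studied the shift difference exceeds the
coupling by a factor of ~70, and the full isotropic Hamiltonian changes
amplitudes only at the 1e−4 level, falling quadratically as the offset
separation grows (both bounds tested). The PASADENA read-out uses a
45° pulse — the optimum for converting `Iz Iz` order into observable
antiphase signal, whose amplitude scales as `sin·cos` of the flip angle —
about +y, so both hydride doublets appear absorptive after zero-order
phasing.

## What the synthetic generator emulates

`generate_dataset()` draws

```
y(τ₂) = A · sin(2π J τ₂) · exp(−2 τ₂ R) + ε,   ε ~ N(0, σ²) i.i.d.
```

on a τ₂ grid; `generate_study()` assembles the full measurement design:
2 complexes × 4 proton→carbon channels × 3 temperatures (256, 261,
267 K), with per-channel couplings and per-temperature decay rates taken
from the packaged parameter table (`complex_parameters()`), `A = 1`, and
σ = 0.02 of the unit amplitude by default — a noise level consistent with
the scatter of the measured kinetics. One channel (Hᵇ→C² of complex 1)
has no observable coupling and is generated as pure noise; recovering its
non-identifiability is part of the test suite.

The generator emulates the *fitted-integral* kinetics, not the raw
spectra: no lineshapes, no phase errors, no exchange-correlated noise,
no enhancement-factor scale (amplitudes are relative throughout, matching
the deviation-density convention). Passing tests therefore demonstrate
that the estimation machinery is correct and calibrated for this signal
model — not that real spectra reduce to it; that reduction (integration
of phased antiphase multiplets) happens upstream of this package.

τ₂ grids default to 30 points over 0.6 s for couplings above 2 Hz. For
sub-hertz channels the window is set by two competing limits: it should
reach one quarter-period `1/(4J)` — with much less of the oscillation,
`A sin(2πJτ)` degenerates to `A·2πJτ` and only the product `A·J` is
determined — but sampling past `τ ≈ 1.5/R`, where the envelope has fallen
below 5%, adds noise-only points. The default is
`max(0.4, min(1/(4J), 1.5/R, 1.2))` s over 40 points. Grid spacings stay
below the Nyquist guard `1/(2·J_max)` with `J_max = 12` Hz.

## Estimation

`fit_single()` minimizes the untransformed least-squares objective with
analytic Jacobians (Levenberg–Marquardt via `minpack.lm`), J constrained
to `[0, 15]` Hz — magnitudes only, honoring the parity of the model — and
R to `(0, 50]` s⁻¹. Because the objective in J has aliased local minima,
every fit is multi-start: a data-driven initializer (dominant discrete
Fourier frequency for J₀; envelope log-slope for R₀; least-squares
projection for A₀, signed so negated data start mirrored) plus a fixed
8-point J grid spanning 0.05–12 Hz. Best final SSE wins; ties break
toward smaller J. Standard errors come from the Jacobian at the optimum
scaled by residual variance.

Two degeneracies are flagged rather than hidden, as
`identifiable = FALSE`:

* *no significant oscillation* — the three-parameter model fails an
  F-test against the zero model at a threshold (F ≥ 50) far above what
  frequency-searching pure noise achieves and far below any genuine
  transfer signal;
* *the A·J ridge* — when the usable window holds only a small fraction of
  the period, the A–J correlation at the optimum reaches −1 to many
  digits (|corr| > 0.9999), cleanly separated from the ≈ −0.99 of
  resolvable sub-hertz channels. The product A·J is still recovered
  accurately; the factors are not, and the flag says so. The packaged
  0.014 Hz channel under complex 1's decay rates is the canonical case.

`fit_global()` fits all datasets jointly with J tied per
(complex, channel) — shared over temperatures and detection modes — and R
tied per (complex, temperature, mode), one free amplitude per dataset.
This mirrors how the measured table is reported, and it is what makes the
weakest observable channels estimable: three temperatures with different
decay envelopes intersect the ridge in different directions. Amplitudes
are deliberately left free per dataset (whether the original analysis
tied them across detection modes is not stated; freeing them is the
conservative choice). Sharing with one dataset per group reproduces
`fit_single()` exactly (tested).

## Exchange and activation analysis

The fitted decay is `R = k_d + R₂`. `dissociation_rates()` subtracts an
assumed hydride transverse relaxation rate — default `R₂ = 1 s⁻¹`, the
typical order of magnitude for hydride protons, configurable and
per-temperature — to give dissociation rates and lifetimes `1/k_d`, with
linear error propagation. `eyring_fit()` regresses `ln(k_d/T)` on `1/T`
(inverse-variance weighted when SEs are supplied):
slope `= −ΔH‡/R_gas`, intercept `= ln(k_B/h) + ΔS‡/R_gas`, CODATA
constants. The regression inverts the forward Eyring equation exactly on
noiseless input for any temperature set (tested to 1e−10), and for
two-point input interpolates with zero residual and undefined SEs.

Activation parameters obtained this way from the packaged three-
temperature rates (≈ 52 kJ/mol for complex 1 with R₂ = 1 s⁻¹) are
reported by the pipeline but carry the full weight of the R₂ assumption;
they are diagnostic output, not calibrated constants.

`optimal_tau()` provides the delay optima: `1/(4J)` without damping, and
the stationary point `atan(πJ/R)/(2πJ)` of `sin·exp` with damping — the
damped optimum always precedes the undamped quarter period, which is why
fast-exchanging complexes are probed with delays shorter than `1/(4J)`.

## Numerical choices

* Matrix exponentials via eigendecomposition of the (always Hermitian)
  generators — exact for the ≤ 16-dimensional spaces used here.
* FIDs evaluated analytically in the Hamiltonian eigenbasis (each
  coherence is one complex exponential), then FFT with exponential
  apodization; receiver phase fixed so in-phase x-magnetization is
  absorptive-positive, with an optional zero-order offset for y-phase
  antiphase read-out.
* LM tolerances tightened to `ftol = ptol = 1e−14` so noiseless
  round trips recover parameters to 1e−9 rather than stalling on the
  shallow sub-hertz objective.
* Degenerate inputs: flat signal → `J₀ = 0` sentinel; singular
  covariance → NA standard errors, never fabricated ones; `R ≤ R₂` →
  an error naming the offending temperature.

## Test problem sizes

The suite runs the master-oracle grid at 3 random coupling draws × 49
delay pairs; replicate studies at 20–50 seeds per channel; the
bias/coverage property at 20 replicates × 6 channels with the
temperature-shared global fit (across-channel median |bias| < 2%, pooled
2-SE coverage within [0.88, 0.995]); and the information-pooling and
multi-start properties at 20 and 15 seeds. These sizes keep the whole
suite around ten seconds while leaving the binomial slack of each bound
explicit in the test.

## Limitations

* Relaxation is a single uniform exponential; no relaxation
  superoperator, cross-correlation, or temperature-dependent R₂.
* Exchange enters only through the decay rate — there is no ligand-swap
  superoperator, so lineshape effects of intermediate exchange are out of
  scope, as are pressure and concentration dependences of the exchange
  mechanism.
* Shaped selective pulses are idealized; hydride pairs closer than
  `2/Δ` in offset violate that idealization and are only warned about.
* The strong-coupling regime (shift difference comparable to J) is
  simulated correctly by the full Hamiltonian but the closed-form
  amplitude law, and hence the fitting model, no longer applies there.
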