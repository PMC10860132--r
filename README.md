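# sabrekin

Sub-hertz ¹H–¹³C J couplings decide whether SABRE (signal amplification by
reversible exchange) can hyperpolarize a metabolite such as pyruvate: they
mediate every coherence-driven transfer of parahydrogen-derived spin order
from the iridium-hydride protons to the carbon of interest, yet they are
invisible in ordinary ¹H spectra because exchange broadening swamps lines
split by less than a hertz. `sabrekin` implements the quantitative workflow
that extracts these couplings — and the lifetimes of the transient
Ir–pyruvate complexes that carry them — from selective spin-order-transfer
kinetics:

* **a density-matrix simulator** for small spin-1/2 systems (rotating-frame
  Hamiltonians, ideal selective pulses, spin echoes, FID acquisition with
  Fourier detection), used to verify the pulse sequences;
* **the transfer sequences themselves**: the PASADENA read-out that shows
  each hydride as an antiphase doublet split by J(H,H), the SEPP τ₁ scan,
  and the selective INEPT transfer SEPP-SPINEPT whose carbon antiphase
  amplitude obeys

  ```
  a(τ₁, τ₂) = sin(2π J_IS τ₁) · sin(2π J_SF τ₂) · exp(−2 τ₂ R)
  ```

  with I, S the hydride protons, F the carbon, and R = k_d + R₂ the
  effective decay (complex dissociation plus transverse relaxation);
* **a seeded synthetic-kinetics generator** parameterized by the packaged
  table of measured shifts, couplings and decay rates for the two
  Ir–pyruvate complexes (2 complexes × 4 proton→carbon channels × 3
  temperatures);
* **estimation**: damped-sinusoid nonlinear least squares, per dataset or
  globally with J shared per channel and R per temperature, with standard
  errors, multi-start protection against aliased minima, and explicit
  flags for channels whose coupling is unidentifiable (zero-signal or
  amplitude–frequency ridge);
* **exchange analysis**: R(T) → k_d(T) = R − R₂, lifetimes 1/k_d, and
  Eyring regression of ln(k_d/T) on 1/T for ΔH‡ and ΔS‡.

## Worked example

Simulate the transfer for the strongest channel of complex 2 (Hᵇ→C², J ≈
2.69 Hz) at 267 K, then fit a noisy synthetic kinetics series:

```r
library(sabrekin)
fx  <- complex_parameters()
sys <- fixture_spin_system(fx[[2]], "C2")
sepp_spinept(sepp_spinept_spec("Ha", "Hb", "C2",
                               tau1_s = 0.038, tau2_s = 0.0798,
                               damping_rate = fixture_rate(fx[[2]], 267)),
             sys)
#> <sequence_result> carbon antiphase amplitude = -0.719129

fit_single(generate_dataset(J_hz = 2.69, R_per_s = 1.91,
                            sigma = 0.02, seed = 1))
#> <fit_result> |J| = 2.6997 +/- 0.0096 Hz, R = 1.908 +/- 0.050 1/s,
#>              A = 1.008 (rms 0.0177)
```

The amplitude −0.719 is sin(2π·(−6.55)·0.038)·sin(2π·2.69·0.0798)·
exp(−2·0.0798·1.91): the density-matrix sequence and the closed form agree
to 1e−8 (the sign of J(H,H) is negative; only |J| is observable). The fit
recovers the generating parameters (2.69 Hz, 1.91 s⁻¹) within one standard
error.

Decay rates convert to lifetimes and activation parameters:

```r
kd <- dissociation_rates(data.frame(temperature_K = c(256, 261, 267),
                                    R_per_s = c(3.16, 4.19, 7.05),
                                    se = c(0.03, 0.04, 0.07)))
kd$lifetime_s
#> 0.463 0.313 0.165       # complex 1 lives ~0.17 s at 267 K
eyring_fit(kd)
#> <eyring_result> dH = 51.82 kJ/mol, dS = -35.16 J/(mol K)
```

The end-to-end pipeline — generate the full 24-dataset synthetic study,
global-fit it, run the exchange analysis, compare against the generating
truth — is one call:

```r
run_recover(study_manifest(sigma = 0.02, seed = 42))
```

It reports every identifiable coupling within its confidence interval and
flags the one channel whose coupling is too small to observe.

## Package layout

| file | contents |
|---|---|
| `R/spin-system.R`, `R/quantum-state.R`, `R/simulate.R`, `R/acquire.R` | spin systems, product operators, Hamiltonians, pulses, evolution, detection |
| `R/sequences.R` | PASADENA, SEPP, SEPP-SPINEPT and the closed-form amplitude |
| `R/fixture.R`, `R/synthetic.R` | packaged parameter table, synthetic kinetics |
| `R/fitting.R`, `R/global-fit.R` | damped-sinusoid fits, shared-parameter global fits |
| `R/eyring.R` | rate decomposition, lifetimes, Eyring regression, delay optimization |
| `R/io.R` | kinetics CSV I/O, study manifests, `run_recover()` |
| `vignettes/transfer-kinetics.Rmd` | the methods vignette |
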