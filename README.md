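# crkinetics

Kinetic analysis of microbial hexavalent-chromium reduction in batch
reactors with cometabolic substrates.

Hexavalent chromium (Cr(VI)) is a soluble, highly toxic pollutant that some
bacteria (e.g. *Serratia* sp.) can reduce to the far less toxic Cr(III).
Reduction works best when the culture is fed cometabolic substrates — a
carbon source (glucose) and, optionally, high-carbon iron filings (HCIF), a
zero-valent-iron-rich medium that acts both as reductant and as a microbial
substrate. `crkinetics` is for environmental microbiologists and
bioremediation engineers who need to turn batch time-course data
(biomass OD600, Cr(VI), glucose vs time) into kinetic parameters:

* **Pseudo-order decay laws** for Cr(VI) disappearance:
  first order `C(t) = C₀·e^(−kt)` and the integrated second order
  `C(t) = C₀/(1 + k·C₀·t)`, fitted in their linearised spaces (`ln C` and
  `1/C` vs `t`) so the estimates are closed-form.
* **Specific growth rate** `µ = d ln X/dt`, with the exponential phase
  located automatically as the contiguous window maximising the R² of the
  log-linear fit.
* **Haldane–Andrews substrate inhibition** for single-substrate growth:
  `µ(S) = µmax·S / (S + S²/K_I + K_S)`, which peaks at `S* = √(K_S·K_I)`.
* **Tertiary Monod cometabolism model**: growth on glucose (C), Cr(VI) (P)
  and HCIF (h) simultaneously,

  ```
  µ = Σᵢ  µmaxᵢ·Sᵢ / (K_Sᵢ + Sᵢ + K₂ᵢ·Sⱼ + K₃ᵢ·Sₖ + K₄ᵢ·Sⱼ·Sₖ)
  ```

  with nine cross-inhibition constants K₂ᵢ/K₃ᵢ/K₄ᵢ quantifying how each
  substrate's use is inhibited by the other two, singly and jointly. The
  nine constants are estimated by bounded multi-start Levenberg–Marquardt
  with the per-substrate base parameters frozen.
* **A batch-reactor ODE simulator** (yield-based mass balances +
  biomass-saturated Cr(VI) reduction) so every fitting stage has a
  ground-truth generator, plus calibrated presets for the binary
  (glucose-only) and tertiary (glucose + HCIF) scenarios.

## Worked example

Generate noise-free growth-rate observations from the reference glucose
Haldane parameters and recover them:

```r
library(crkinetics)

p <- haldane_params(mu_max = 0.1129, K_S = 0.5, K_I = 1.01)
p
#> Haldane-Andrews parameters
#>   mu_max: 0.1129 h^-1   K_S: 0.5 mg/L   K_I: 1.01 mg/L
#>   peak: mu = 0.0469011 h^-1 at S* = 0.710634 mg/L

dat <- generate_mu_dataset(p, exp(seq(log(0.05), log(20), length.out = 10)))
fit_haldane(dat, n_starts = 20, seed = 42)
#> Nonlinear least-squares fit (20 starts, seed 42)
#>   R^2 = 1.0000, residual norm = 8.84539e-18, converged: TRUE
#> Haldane-Andrews parameters
#>   mu_max: 0.1129 h^-1   K_S: 0.5 mg/L   K_I: 1.01 mg/L
#>   peak: mu = 0.0469011 h^-1 at S* = 0.710634 mg/L
```

The fit returns the generating `µmax` (0.1129 h⁻¹, the maximum specific
growth rate) and `K_I` (1.01 mg/L, the inhibition constant) exactly, with
`K_S` the half-saturation constant. The full pipeline — simulate every
study Cr(VI) level (10–100 mg/L), estimate µ per replicate, fit both rate
orders per condition, fit the three Haldane models and the tertiary
interaction constants, and write JSON/CSV reports — is one call:

```r
report <- run_analysis("set2_tertiary", seed = 5, noise_cv = 0, out_dir = "out")
```

or from a shell, `exec/crkinetics run-all --input set2_tertiary --seed 5
--out out`. Reports are byte-identical under a fixed seed.

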