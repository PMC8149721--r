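---
title: "Growth and reduction kinetics of Cr(VI) cometabolism: models, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth and reduction kinetics of Cr(VI) cometabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crkinetics)
```

## The system

A chromium-reducing bacterium (a *Serratia* isolate in the motivating
experiments) is grown in 250 mL batch reactors at 35 °C and 120 rpm with an
initial Cr(VI) spike of 10–100 mg/L. Two substrate systems are compared:
the **binary** system (bacteria + 1 g glucose per bottle) and the
**tertiary** system (bacteria + 1 g glucose + 1 g high-carbon iron
filings, HCIF). Samples every 12 h give triplicate time courses of biomass
(OD600), Cr(VI) (mg/L) and glucose (mg/L). The analytical questions are
kinetic: how fast does Cr(VI) disappear, how fast do the cells grow, and
how strongly do the three substrates inhibit each other's use?

HCIF is an insoluble solid with no aqueous concentration. So that it can
enter concentration-based growth laws, its dose is expressed per litre of
reactor liquid (`dose_mg_per_l()`): 1 g/250 mL ↦ 4000 mg/L. This is a
bookkeeping convention, not a solubility claim.

## Models

**Pseudo-order decay.** Cr(VI) disappearance is summarised by
$C(t) = C_0 e^{-kt}$ (first order, $k$ in h⁻¹) or by the integrated
second-order law $C(t) = C_0/(1 + k C_0 t)$ ($k$ in mg⁻¹ L h⁻¹), obtained
from $1/C - 1/C_0 = kt$. Hours are used throughout: every time axis in the
motivating study is in hours and the tabulated constants carry h⁻¹ units.
`fit_rate_constant()` fits both laws **in their linearised spaces**
($\ln C$ or $1/C$ against $t$): the estimates are then closed-form,
trivially reproducible, and the R² values refer to the linearised fit, the
convention under which the reference constants were tabulated. Points at or
below a detection limit (default 0.05 mg/L) are excluded — complete
reduction produces zeros that neither transform accepts. A series with
fewer than two usable points is an error; exactly two points give the
closed-form two-point rate.

**Specific growth rate.** $\mu = d\ln X/dt$, evaluated over the
exponential phase. "Exponential phase" is made operational in
`estimate_mu()`: among all contiguous windows of at least `min_window`
(default 3) points above a detection floor (default 0.01 OD), pick the one
maximising the log-linear fit R², breaking ties toward longer windows and
then earlier starts. The procedure is deliberately simple enough to check
against an exhaustive brute-force search, which the test suite does for
every series length up to 30. A perfectly flat window is a perfect
zero-slope fit (R² = 1), so a constant culture yields $\mu = 0$ rather
than an error. Replicates are estimated separately and summarised as
mean ± SD, matching the triplicate design. µ is unit-free under the log
transform, so no OD600-to-dry-weight conversion is needed or attempted.

**Haldane–Andrews growth.** Single-substrate growth with self-inhibition:
$$\mu(S) = \frac{\mu_{max} S}{S + S^2/K_I + K_S},$$
rising to a peak $\mu_{max}/(1 + 2\sqrt{K_S/K_I})$ at
$S^* = \sqrt{K_S K_I}$ and declining beyond. The reference fits report
$\mu_{max}$ and $K_I$ for each substrate (Cr(VI): 0.002346 h⁻¹, 134.12
mg/L; glucose: 0.1129 h⁻¹, 1.01 mg/L; HCIF: 0.1923 h⁻¹, 11.99 mg/L) but
never $K_S$, which is therefore a free parameter everywhere in this
package. The recovery experiments fix conventional values (0.5 mg/L for
glucose, 5 mg/L for Cr(VI) and HCIF; `single_substrate_reference()`) purely
to have a complete generating truth.

**Tertiary Monod cometabolism.** Growth on glucose (subscript C), Cr(VI)
(P) and HCIF (h) together:
$$\mu = \sum_{i \in \{C,P,h\}} \frac{\mu_{max,i} S_i}
{K_{S,i} + S_i + K_{2i} S_j + K_{3i} S_k + K_{4i} S_j S_k}.$$
The nine interaction constants measure inhibition of substrate $i$'s use
by one other substrate ($K_{2i}$, $K_{3i}$) or both jointly ($K_{4i}$);
all nine zero decouples the system into independent Monod terms. The
published Cr(VI) term carries $S_C$ in its denominator's saturation slot
where symmetry with the other two terms implies $S_P$; since the printed
form would make chromium's saturation depend on glucose — contradicting
the stated meaning of the interaction terms — the package defaults to the
symmetry-corrected form (`form_variant = "symmetric"`) and keeps the
printed one selectable (`"as_printed"`). The reference interaction table
(`interaction_products_reference()`) reports **products** K·S, not bare
constants (its row labels say so); the package stores constants and
substrate states separately and converts in both directions
(`interaction_constants_from_products()`, `interaction_products()`).

## Fitting machinery

`fit_haldane()` and `fit_tertiary()` minimise the absolute residual sum of
squares by multi-start Levenberg–Marquardt (`minpack.lm::nls.lm`) inside
the box $[10^{-6}, 10^4]$ per parameter. Choices that matter:

* **Log-parameter space.** Each start optimises $\log\theta$: positivity
  is structural and a spread of six orders of magnitude among constants
  (common between $K_4$ and $K_2$ values) does not wreck conditioning.
* **Linear-space polish.** Log scale flattens the objective near weakly
  determined constants, so each converged start is re-polished by a second
  LM pass in linear space; the better of the two is kept. Without this
  step the nine-constant recovery stalls in shallow valleys.
* **Seeded, prefix-stable starts.** Starts are drawn log-uniformly over
  the box as one sequential RNG stream from a mandatory seed, so
  best-of-$n$ is reproducible and the start set for $n$ starts is a prefix
  of that for $n+1$ (the best objective is monotone in `n_starts`,
  default 20).
* **Frozen base parameters.** In the tertiary fit the per-substrate
  $(\mu_{max}, K_S)$ come from the single/binary-substrate stage and are
  never re-estimated — only the nine interaction constants are free. A
  design without variation in some substrate cannot identify that
  substrate's constants; the fit attaches an identifiability warning
  rather than failing.
* **Degenerate data.** An all-zero growth signal converges to the lower
  bound and is flagged `degenerate`; R² is reported as `NA` because the
  total sum of squares vanishes. R² elsewhere uses the conventional
  about-the-mean definition and is clipped to [0, 1] only in rate-fit
  reporting.

Recovery behaviour, verified in the test suite: noise-free data generated
from the reference constants return $\mu_{max}$ within 0.5% and $K_I$
within 2% (in practice to machine precision) on 10-point log-spaced grids
spanning each growth peak, and all nine interaction constants within 5%
(again, in practice exactly) on a 3×3×3 factorial design. The recovery
design uses balanced base rates ($\mu_{max,P} = 0.05$ h⁻¹ rather than the
tiny chromium value) and constants sized so each K·S summand moves its
denominator appreciably: with the reference products themselves
(≤ 1.6 at denominators of thousands) the constants' influence on µ is
below $10^{-3}$ relative and no least-squares procedure could pin them
from 27 noise-free points — parameter recovery is a property of the
design as much as of the optimiser.

## The simulator

`simulate_batch()` integrates (via `deSolve::lsoda`, rtol 1e-8, atol
1e-10) the minimal yield-based mass balances
$$\frac{dX}{dt} = (\mu - k_d\,\mathbf{1}[\text{exhausted}])X, \quad
\frac{dS_C}{dt} = -\frac{\mu_C X}{Y_C}, \quad
\frac{dS_h}{dt} = -\frac{\mu_h X}{Y_h}, \quad
\frac{dS_P}{dt} = -\frac{q_P X S_P}{S_P + K_{red}},$$
where $\mu_C,\mu_h$ are the glucose/HCIF terms of the growth law, $Y$ are
biomass yields, $q_P$ a specific reduction rate and $K_{red}$ a small
saturation constant making reduction first-order in Cr(VI) near zero.
These forms are the package's own standard constructions — chosen so every
fitting stage has a generator with known truth — and are not mechanistic
claims about Fe⁰/Fe(II)/Cr(VI) electron transfer. Biomass decline after
substrate exhaustion is first-order decay switched on when total growth
substrate falls below a threshold (default 10 mg/L ≈ 0.25% of the glucose
dose), the simplest mechanism producing the observed post-peak decline.
Measurement noise is multiplicative Gaussian (default CV 5%, triplicates),
drawn from a seeded stream; the noise-free trajectory is always returned
alongside the replicates, including the (unmeasurable) HCIF state.

**Presets.** The scenario presets are calibrated once to the study's
qualitative milestones and then left alone:

* `set1_binary` — Haldane growth on glucose. The reference glucose
  constants are interpreted on the g/L scale ($K_S$ = 500, $K_I$ = 1010
  mg/L): taken literally in mg/L, $K_I$ = 1.01 at 4000 mg/L glucose gives
  $\mu \approx 3\times10^{-5}$ h⁻¹ and nothing would grow. With
  $Y_C = 5\times10^{-5}$ OD/(mg/L) and $q_P$ = 3.5, glucose is exhausted
  near 60 h, biomass peaks and declines, low Cr(VI) levels (10 mg/L) are
  fully reduced by ~50 h, and ≥ 5% of a 100 mg/L spike remains at 90 h.
* `set2_tertiary` — tertiary Monod growth using the reference interaction
  constants (10 mg/L column inverted at state 4000/10/4000 mg/L) with base
  rates calibrated ($\mu_{max,C}$ = 0.02, $\mu_{max,h}$ = 0.03 h⁻¹) so
  growth is sustained to ~120 h, both growth substrates deplete near 120
  h, and a 100 mg/L spike is reduced below 1% by 120 h.
* `first_order` — a non-growing culture with $K_{red}$ (1000 mg/L) far
  above the Cr(VI) level, so the decay is exponential with the exactly
  known constant $k = q_P X_0/K_{red}$ = 0.057 h⁻¹. This closes the loop
  between simulator and rate fitter (recovered within 5%; in practice
  0.2%, the residual curvature from $S_P/K_{red} \le 1\%$).

**What the simulator does and does not emulate.** It reproduces the
lag/log/decline biomass shape, sigmoidal-to-complete Cr(VI) decay,
monotone substrate depletion, triplicate structure and multiplicative
noise. It does **not** emulate Cr(VI) toxicity to growth in the binary
preset (growth there depends on glucose only), diauxic switching, pH or
temperature effects, or stochastic population dynamics. Passing recovery
tests therefore demonstrate that the estimators invert the package's own
generating laws under realistic noise — not that those laws are the true
biology of any particular isolate.

## Pipeline and reporting

`run_analysis()` binds the stages and emits a versioned JSON report plus
flat CSVs shaped like the familiar rate-constant and interaction-product
tables, with full provenance (input MD5, seed, options, package version)
and byte-identical output under a fixed seed. With preset input the
Haldane and tertiary stages run as recovery experiments against the
reference constants; with CSV input the Cr(VI) Haldane stage uses the
per-condition (cr0, mean µ) pairs when at least four distinct levels are
present, and stages whose designs a single batch file cannot supply
(glucose/HCIF dose variation, multi-substrate µ designs) are marked
`skipped` rather than silently dropped. Reported reduction percentages use
the final sampled value — narrative "complete reduction" times fall
between samples, and the report states the first sampled time below the
detection limit rather than interpolating.

Problem sizes throughout (10-point grids, 27-point factorial, 11-point
time courses, 20 starts, 30-replicate noise study in the tests) were
chosen as the smallest designs on which the recovery tolerances above are
comfortably met; the entire suite runs in seconds.

## Known limitations

* $K_S$ values are unidentifiable from the reference reports; all
  recovery statements are conditional on the conventional choices.
* The reference interaction products cannot be inverted to recoverable
  constants on desk-scale designs (see above); the acceptance surface for
  the tertiary model is recovery on synthetic designs, not reproduction
  of the published product table.
* `estimate_mu` assumes a single exponential phase; diauxic curves will
  yield the better-fitting of the two phases.
* The as-printed tertiary variant is provided for fidelity but its Cr(VI)
  term saturates in glucose; quantitative conclusions should use the
  symmetric default.
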