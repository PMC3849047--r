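---
title: "Modelling nanoparticle effects on mouse lung surfactant and mechanics"
author: "nanolung"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nanoparticle effects on mouse lung surfactant and mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanolung)
```

# The biological system and the model

Pulmonary surfactant — a mixture of roughly 90% phospholipids (PL) and 10%
proteins — lines the alveolar air–liquid interface and keeps the lung
inflatable by lowering surface tension. The package models three lumped
species: PL, the surface-active proteins SP-B/SP-C (SA), and the collectins
SP-A/SP-D (C). Inhaled nanoparticles that reach the alveoli are arrested by
the interfacial film, bind PL into a surface corona, are flushed into the
lining fluid, and are then taken up by alveolar cells or cleared. Surfactant
depletion at the interface feeds through to whole-lung mechanics, which is
described with a surfactant-coupled Constant Phase Model (CPM) of
respiratory impedance.

The simulator couples four pieces:

1. **Surfactant homeostasis** — a 5-compartment × 3-species mass-balance
   ODE system (15 equations): type II cell pool (AT2), lamellar bodies
   (LB), alveolar fluid (AF), interface (Int), and an absorbing `Loss`
   compartment collecting degradation and airway loss. Amounts are in
   µmol per g lung, time in minutes.
2. **Particle–surfactant binding** — Michaelis–Menten depletion of
   interfacial PL by free particle surface area,
   `V_A · A/(K_A + A)`, with the area–PL coupling set by a 4 nm coat of
   molar density 1439.6 µmol/ml (1040 mg/ml at the mean PL molecular
   weight of 722.445 g/mol).
3. **Cellular uptake and elimination** — adhesion-gated Michaelis–Menten
   uptake by AT1, AT2 and macrophages, plus lumped first-order elimination.
4. **Lung mechanics** — the CPM
   `Z(ω) = R + iωI + (G − iH)/ω^α`, `α = (2/π)·atan(H/G)`, with
   `R`, `G`, `H` scaled linearly by the relative interfacial PL deficit.

# Surfactant kinetics

Per species *i*, with starred rates regulated as described below:

- `dAT2/dt = Gen + K_Re* · AF − (K_Sec* + K_CSec) · AT2`
- `dLB/dt  = K_Sec* · AT2 − K_LB · LB`
- `dAF/dt  = K_LB · LB + K_CSec · AT2 + K_Des · Int − J_Ad −
  (K_Re* + K_Deg + K_AW) · AF`
- `dInt/dt = J_Ad − K_Des · Int − J_NP`
- `dLoss/dt = (K_Deg + K_AW) · AF`

with adsorption flux `J_Ad = K_Ad* · AF · max(0, 1 − Int/M_eq)` and `J_NP`
the nanoparticle binding sink (PL only). Direct secretion `K_CSec` exists
only for collectins. Summing the five balances gives
`d(total)/dt = Gen − (K_Deg + K_AW)·AF`, so at any steady state the fluid
amount is pinned at `AF* = Gen/(K_Deg + K_AW)` — a structural identity that
drives several calibration choices below.

## Regulation

Surfactant proteins regulate the delivery processes: SA and C activate
adsorption, C inhibits secretion and activates recycling. Each effect is a
linear-in-concentration factor: activation multiplies the base rate by
`1 + Σ k·c`, inhibition divides by it (so inhibited rates stay positive,
and multiple activators combine additively inside one factor, consistent
with independently estimated constants). The regulator input is the AF
concentration of the species (amount × lung mass ÷ alveolar fluid volume;
0.2482 ml for the 24.82 g reference mouse at 10 ml/kg).

**Concentration scale.** The regulatory constants are tabulated per
µmol/ml, while the regulator concentrations are specified in mol/ml. The
default calibration evaluates the factors with concentrations on the
mol/ml scale, which makes the regulatory corrections small (relative size
10⁻⁵–10⁻³) at physiological concentrations. This is a deliberate choice:
if the factors are instead evaluated on the µmol/ml scale they reach
45–6000×, under which the recycling activation term alone exceeds the
entire AT2 secretion flux and the generation closure becomes negative for
PL — no non-negative steady calibration of the published rate table
exists. The scale is a config switch
(`regulation$concentration_scale`), and `regulated_rate()` itself is
scale-agnostic.

## Calibration by steady-state closure

The reference amounts (AT2, LB, AF, Int per species) are treated as the
physiological steady state, and three groups of constants are closed
against them:

- **Generation** `Gen_i = (K_Sec* + K_CSec)·AT2 − K_Re*·AF`, which pins
  the AT2 balance.
- **Degradation** `K_Deg,i = Gen_i/AF_i − K_AW`, which pins the long-run
  fluid amount at its reference value via the structural identity above.
  The LB pool is treated as pass-through in this balance (its throughput
  equals AT2 secretion): the lamellar body is a transient organelle with
  no biological steady state, so it is excluded from the stationarity
  requirement and relaxes to `K_Sec*·AT2/K_LB` during the pre-run. The
  published optimized degradation constants are not recoverable from the
  steady-state balances (with them the fluid PL would settle an order of
  magnitude below its reference amount), so the closure values
  (PL 4.65×10⁻³, SA 1.88×10⁻³, C 1.40×10⁻² min⁻¹) are the package
  defaults; the `rates$K_Deg` entries can be overridden numerically.
- **Equilibrium film amounts** `M_eq`: closed from the interface balance
  `K_Ad*·AF·(1 − Int/M_eq) = K_Des·Int` where the implied film factor is
  feasible (collectins); where desorption outflow exceeds the maximal
  adsorption inflow (PL, SA under the optimized adsorption constants) the
  closure is infeasible and `M_eq` falls back to twice the reference
  interface amount, letting the interface relax to its own smaller fixed
  point during the pre-run.

`surf_steady_state()` returns the resulting fixed point; all twelve
non-Loss balances vanish there to machine precision, and a ten-day
integration started from the *printed* reference amounts (including the
non-stationary LB and Int entries) returns the fluid PL to within 0.1% of
its reference 0.0818 µmol/g.

Non-identifiable constants can also be estimated explicitly
(`estimate_missing_rates()`, verified by a synthetic roundtrip against a
long integration), and the whole rate table can be refined by constrained
least squares on the stationarity residuals (`refine_parameters()`;
residuals are relative drift per day, penalty `λ = 10⁻²` on squared
log-deviation from the initial estimates, bounds 0.1–10×; the objective
is the package's own choice — published accounts name only the optimizer).

# Particle binding, transport, uptake

A dose `m` of monodisperse spheres maps to a number density
`m/(ρ·πd³/6)/V_AF`. Intratracheal instillation delivers 52.18% of the dose
to the pulmonary region; inhalation of 15 nm particles delivers 40.26%.
The bolus enters as naked particles at the interface. Binding converts
naked to coated particles at the population level through area
bookkeeping: one particle is "coated" when its full capacity
(surface area × 4 nm × 1439.6 µmol/ml ≈ 4.1×10⁻¹⁵ µmol for 15 nm) of PL is
bound. The Michaelis–Menten binding rate is throttled by a smooth factor
`Int_PL/(Int_PL + 10⁻³)` so the sink cannot overdraw the interfacial pool:
with the optimized PL adsorption constant the interface holds much less PL
than the coating demand of a 10 µg/g dose, so the coating rate is limited
by adsorption resupply from the fluid and the coating episode stretches
over roughly a day, rather than the seconds the unthrottled in vitro rate
would imply.

Coated particles move to the fluid at 10 min⁻¹ (a fast first-order
stand-in for per-breath surfactant cycling that keeps the system an ODE);
naked particles transfer at `f = 0.01 min⁻¹`, a provisional config value
with no published counterpart. Uptake per cell is
`P_adh · V_max · n/(K_m + n)` with adhesion probability
`P = clamp(γ(1−φ)/d_c · F_size(d_p) · F_zeta(ζ), 0, 1)`; coated particles
carry the corona zeta potential of −39.2 mV. The size/zeta affinities are
monotone piecewise-linear interpolants over config knot tables normalized
to [0, 1] — placeholders standing in for the cited in vitro
dose–response curves, swappable once digitized. `γ`, `V_max`, `K_m` and
the AT1 census are likewise literature-guided defaults (phagocytosis
`V_max` 10 min⁻¹cell⁻¹ vs endocytosis 1 min⁻¹cell⁻¹; `K_m` 5×10⁸ and 10⁹
ml⁻¹; γ of 500 for macrophages reflecting their far higher intrinsic
avidity; 3.3×10⁷ AT1 cells), chosen once so that per-cell burdens order
Mph > AT1 > AT2 as observed. Elimination is lumped first-order at
3.511×10⁻⁴ min⁻¹; the order of magnitude of this constant is poorly
constrained by the available reports, so the −4 exponent is provisional
and config-exposed.

Reported "total PL" is free fluid PL plus PL bound to particles suspended
in the fluid, matching what lavage would collect. Under the default
10 µg/g silver scenario the total rises by a few percent, peaks once the
particle population is fully coated (around day 1), and resolves by day 7
as coated particles are cleared. The measured response in mice peaks
nearer day 3; the model peaks earlier because inflammation-driven
secretion upregulation (a separate module of the original system) is
deliberately out of scope here.

# Mechanics

`cpm_impedance()` evaluates the CPM on a Hz grid (converted internally to
rad/s); `rrs_ers()` uses the convention `Rrs = Re Z`, `Ers = −ω·Im Z`, so
a positive tissue elastance gives positive Ers at low frequency (sign
conventions vary; this is the standard forced-oscillation one, isolated
in a single function and trivially flippable).
`cpm_fit()` is Levenberg–Marquardt least squares on the stacked real and
imaginary residuals with unit weights; `α` is always derived from
`(G, H)`, never fitted independently. Coupling coefficients `k_R, k_G,
k_H` are the least-squares slopes through the origin of `X*/X − 1`
against the deficit `ΔCs = (Cs_ref − Cs)/Cs_ref`, where `Cs` is the
interfacial PL amount and `Cs_ref` its control steady state —
dimensionless, zero at control, positive under depletion.

# Sensitivity analysis

`run_sensitivity()` perturbs each of 46 parameters one at a time by +10%
(config-exposed) and reports the normalized elasticity
`S = (ΔV/V)/(Δp/p)` of four outputs — PL, SA, C amounts and particle
number density in the fluid — at day 3 after the default 10 µg/g silver
dose, the time of maximal response. The census (declared explicitly in
the config) groups 10 physiological constants
(the morphology table), 30 biochemical ones (22 rate entries, 4
regulatory constants, 3 equilibrium film amounts, elimination) and 6
particle-specific ones (diameter, density, zeta, `V_A`, `K_A`, `f`).
Perturbations apply to the *calibrated* constants — generation is derived,
not a parameter, and re-deriving closures after each perturbation would
simply re-center the system and null every index. Morphology entries that
do not enter this reduced formulation (lung volume, alveolar surface
area, interface thickness, cell and organelle volumes, LB census) come
out with S = 0; that is an honest statement about this model, not a
numerical artifact.

# Numerical choices

- Stiff integration with `lsoda`, rtol 10⁻⁸, atol 10⁻¹² µmol/g for
  surfactant states and 10⁻¹² × the deposited density for particle
  states; fluxes are evaluated on the non-negative part of the state,
  which guards trajectories against negative amounts.
- Particle number is conserved exactly by construction; the default
  7-day run conserves it to ~10⁻¹⁵ relative.
- Output every 10 min by default (1 min available via config); tests and
  examples use coarser grids of 1–12 h, which changes nothing but the
  sampling of the reported trajectories.
- Test problem sizes: 10-day pre-runs plus 3–7 day exposures; 50-replicate
  Monte-Carlo for spectrum-fit bias; 20-draw property loops. These are the
  package's chosen verification sizes.

# Known limitations

- Inflammation/cytokine dynamics and their feedback on protein secretion
  are not modelled; consequently the late (day-3) peak and the
  dose-dependent sign changes in the fitted coupling coefficients seen in
  vivo are outside what this package can reproduce.
- The measured mouse impedance spectra are not published as tables, so the
  mechanics module is verified against synthetic spectra (self-consistency
  and noise-recovery), not against the in vivo figures.
- The corona is PL-only; SP-A/SP-D binding to particles is not a separate
  sink. Translocation routes are lumped into one elimination constant.
- Affinity curves, uptake kinetics and the naked-transfer fraction are
  placeholder parameterizations; conclusions that hinge on their absolute
  values (rather than orderings) should be treated as illustrative.
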