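---
title: "The colimitation model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The colimitation model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colimitr)
library(dplyr)
```

## The model and its assumptions

`colimitr` treats a single cell as two well-mixed inorganic-carbon pools,
intracellular CO₂ (`C_in`) and HCO₃⁻ (`H_in`), exchanging with fixed
extracellular boundary concentrations and coupled by interconversion:

$$\frac{dC_{in}}{dt} = \alpha(C_{out}-C_{in}) + \left(k_d + \tfrac{\delta}{K}\right)H_{in} - (k_h+\delta)C_{in} - \gamma C_{in}$$
$$\frac{dH_{in}}{dt} = \chi S_{ext} + \beta(H_{out}-H_{in}) + (k_h+\delta)C_{in} - \left(k_d + \tfrac{\delta}{K}\right)H_{in} - \varphi H_{in}$$

All processes are first-order, which buys three structural properties: the
steady state is the exact solution of a 2×2 linear system (no solver
tolerance beyond machine precision), every flux is proportional to the
boundary concentrations, and conservation
$J_\chi - J_{L,tot} = J_{rub} + J_{bic}$ holds identically. The model
deliberately omits enzyme saturation, rubisco oxygenation, carboxysome
compartmentalization (interior pH, shell permeability) and O₂ chemistry: it
is built for coarse, order-of-magnitude comparisons between physiological
regimes, not for fitting growth curves.

Growth is a Liebig minimum over the two carboxylation fluxes. A fraction
$f_H$ of biomass carbon must come from HCO₃⁻-dependent carboxylations
(lipid, nucleotide, arginine biosynthesis); the rest comes from rubisco:

$$\mu = \min\!\left(\frac{J_{rub}}{(1-f_H)\,q_C},\ \frac{J_{bic}}{f_H\,q_C}\right)\cdot 3600 \ \ \mathrm{h^{-1}},\qquad \text{optionally}\ \mu \le \mu_{max}.$$

The minimum (rather than a multiplicative law) produces the sharp two-regime
behaviour — rubisco-limited vs bicarboxylation-limited — that the package's
sweep tests assert; a multiplicative law would blur the regime boundary.
Exact ties classify as rubisco-limited, a deterministic tie-break.

## Parameters, units, defaults

Concentrations are µM, rate constants s⁻¹, growth rates h⁻¹; conversions are
centralized in `growth_prediction()` and `percell_fixation_rate()`.

| Parameter | Default | Why |
| --- | --- | --- |
| `k_h` | 0.037 s⁻¹ | textbook uncatalyzed CO₂ hydration at 25 °C; gives a ~22 s relaxation time at pH 7 |
| `pK1_eff` | 6.35 | effective first pKa of CO₂/HCO₃⁻ |
| `K_H` | 0.034 M/atm | Henry solubility; 0.04% CO₂ → 13.6 µM dissolved |
| `P_C` | 0.3 cm/s | middle of the measured 0.1–1 cm/s range |
| `sa_v` | 3.33×10⁴ cm⁻¹ | 1 fL cell; makes α = P_C·SA/V = 10⁴ s⁻¹ exactly |
| `P_H` | 3×10⁻⁸ cm/s | anion permeation of bilayers is many orders slower than CO₂ (β = 10⁻³ s⁻¹). A much larger value would let passive HCO₃⁻ influx alone satisfy the anabolic demand above ~0.5% CO₂, erasing the CA/transporter growth benefit the model exists to explain |
| `gamma` | 90 s⁻¹ | see below |
| `delta`, `chi` | 0 | host without CCM components |
| `phi` | 1 s⁻¹ | fast enough that HCO₃⁻ *supply* (interconversion + transport), not the carboxylases themselves, limits `J_bic` |
| `f_H` | 0.02 | a small minority of biomass carbon comes from HCO₃⁻ |
| `q_C` | 1.66×10⁷ µM | ≈10¹⁰ carbon atoms per 1 fL cell |
| `mu_max` | ∞ (core), 0.25 h⁻¹ (genotypes) | see below |

**Choosing `gamma = 90 s⁻¹`.** Only the ceiling γ < 10³ s⁻¹ is physically
fixed (≈1 mM rubisco sites at most). The default was set by closed-form
analysis of the model so that three qualitative facts hold simultaneously:
(i) the bare-rubisco cell is bicarboxylation-limited (demand
$\tfrac{f_H}{1-f_H}\gamma C \approx 1.8\,C$ exceeds the spontaneous supply
$(k_h + \beta K)C \approx 0.04\,C$); (ii) a CCM-complete cell reaches the
host growth ceiling even at ambient CO₂
($3600\,\gamma C_{out}/((1-f_H)q_C) > \mu_{max}$ at 13.6 µM), which is what
makes acquisition trajectories fitness-positive as CO₂ declines; and
(iii) the futile-cycle asymptote
$(\alpha+\beta K)/(\gamma+\varphi K) \approx 106$ exceeds 100, the observed
order of extreme leakage. These are properties of the model's structure,
derived before any tests were run against them.

**The growth ceiling `mu_max`.** A purely linear model predicts growth
proportional to `C_out` forever, so a CCM would help at *every* CO₂ level —
contrary to the observation that CCMs are dispensable at 5–10% CO₂. The
genotype module therefore caps growth at 0.25 h⁻¹ (2.8 h doubling),
representing limitation by energy and nutrients outside the carbon model.
The core model and the sweep engines keep `mu_max = Inf` so that linearity
properties (e.g. halving growth when doubling `q_C`) hold exactly.

**CA is Haldane-consistent.** δ accelerates hydration and dehydration in the
ratio fixed by the equilibrium constant at cytosolic pH, so an arbitrarily
fast CA leaves an equilibrated pool pair untouched (a property test). A CA
that shifted equilibrium would be a perpetual-motion machine.

**Uptake substrate.** χ acts on external CO₂ by default (vectorial
hydration, DAB-like), delivering HCO₃⁻ to the cytosol; a flag switches the
substrate to external HCO₃⁻ (SbtA-like). Both deliver to `H_in` — that is
what "energized Ci uptake generates intracellular HCO₃⁻" means mechanically.

## Scenario operations

* `leakage_heatmap()` sweeps δ ∈ [10⁻¹, 10⁵] and χ ∈ [1, 10⁶] s⁻¹ (six
  decades each, spanning the genotype defaults δ = 100, χ = 5). The upper χ
  end must exceed α ≈ 10⁴ s⁻¹, otherwise the leak ratio cannot approach its
  asymptote; χ ≈ 10⁶ s⁻¹ is deliberately unphysiological — the point of the
  corner is that extreme coexpression wastes ~100× more Ci than it fixes.
  The zero-leakage contour is found by bisection in χ at each δ (relative
  tolerance 10⁻⁶).
* `depletion_scan()` uses the naive setting δ = χ = φ = 0, so the frontier
  where `C_in/C_out` crosses 0.5 reduces to the closed form γ = α (tested to
  1%).
* `pump_scenario()` asks when uptake + CA can hold `C_in ≥ 2·C_out`
  ("substantially above" is operationalized as twofold, the smallest
  unambiguous multiple, recorded in the result's attributes). δ is set to
  the high end of the leakage sweep. χ defaults to
  `2 × 1.1 × (γ + φK)` ≈ 208 s⁻¹: the uptake capacity needed to supply the
  total carboxylation demand of a twofold-elevated internal pool, with 10%
  headroom. Sizing χ this way keeps the scenario honest — an uptake rate
  far above α would "pump" even at the measured permeability, which would
  make the question trivial rather than answer it. The threshold reduction
  factor is refined by root-finding between grid points.

## Genotypes and trajectories

A genotype toggles δ (CA), χ (transporter) and a carboxysome annotation.
The carboxysome has **no mechanistic effect** here: a compartment model is
out of scope, so carboxysome acquisition steps are marked unscored and
orderings differing only in when the carboxysome arrives score identically.
`delta_on = 100` and `chi_on = 5` sit inside the zero-leakage-feasible
region of the (δ, χ) plane — the complete genotype has negative total
leakage (net passive influx), i.e. modest coexpression, not futile cycling.

`enumerate_trajectories()` evaluates the six acquisition orders on a
declining schedule 5% → 1.5% → 0.5% → 0.04% CO₂ (the assay ladder), the
ancestral rubisco-only genotype at the first level and each acquisition at
the next. "Fitness positive" is taken as *non-decreasing* growth along the
path: an acquisition counts as favourable if it at least compensates the
CO₂ decline at which it is evaluated (requiring strict increase would make
the neutral carboxysome step disqualify every trajectory).

## Fitness statistic

Strain fitness is `log2((f_end + ε)/(f_T0 + ε))` on within-sample relative
abundances, ε = pseudocount / sample total (pseudocount 0.5 reads). Gene
fitness is the unweighted mean over a gene's insertion strains passing a
T₀ filter (≥ 3 reads); genes with no passing strain are flagged, never
silently dropped. Unweighted averaging matches "the average effect of
multiple distinct mutants"; variance-style weighting by T₀ depth is
available behind `weighted = TRUE`. No between-sample normalization is
applied: in a mostly-neutral library the compositional offset
$-\log_2 \sum_i f_{i,0} 2^{d w_i}$ is small, and the recovery tests bound it
together with sampling noise.

## What the synthetic generator does and does not emulate

`simulate_library()` draws 32–44 insertions per gene (realized library mean
within the 35–40 typical of barcoded transposon libraries), log-normal
initial strain frequencies, 6.5–7.5 competitive doublings per replicate,
deterministic exponential selection
$f_i \propto f_{i,0} 2^{d(1+w_i)}$ with $w_i = \mathrm{effect}_i/d$, and
multinomial read sampling at 10⁶ reads/sample (a plausible MiSeq-scale
depth). It does **not** model sequencing error, chimeric barcodes, PCR
jackpots, strain-specific insertion-position effects (within-gene effect
variance defaults to 0, configurable), or bottlenecks during growth — so a
passing recovery test shows the statistic is unbiased under multinomial
sampling, not that it is robust to every artifact of real BarSeq data.
`simulate_growth()` produces logistic OD curves (inoculum 0.005 OD,
carrying capacity 0.5 OD, additive Gaussian noise sd 0.01, 30-min sampling)
whose rates come from the genotype model; it does not emulate lags,
diauxie, or evaporation.

## Numerical choices

* Steady state: `solve()` on the 2×2 system; singularity (all removal terms
  zero with nonzero input) raises a degenerate-parameter error rather than
  returning junk; negative solutions are impossible for valid parameters
  (M-matrix) and are asserted against.
* The independent oracle in the test-suite integrates the two ODEs with
  `deSolve::lsoda` (rtol 10⁻¹², 80 e-foldings of the slowest mode) and
  agrees with the linear solve to 10⁻⁶ relative over 100 log-uniform random
  parameter sets.
* Monotonicity of growth in δ holds only to ~10⁻⁴ relative: while `H_in` is
  below equilibrium, CA drains `C_in` by at most ~φK/α relative, so the
  rubisco-limited branch can dip infinitesimally. Tests assert monotonicity
  within 10⁻³ relative.
* Problem sizes: sweeps default to 25 points per axis (25×25 grids solve in
  well under a second); the ODE-oracle suite uses 100 random parameter
  sets; library recovery uses 80–100 genes at 10⁶ reads and two replicates.

## Known limitations

* No carboxysome mechanism: the model cannot address shell permeability,
  interior pH, or why encapsulation (rather than cytosolic CA) is the
  evolutionary endpoint.
* Linearity means genotype *ratios* of growth are CO₂-independent below the
  ceiling; all CO₂-dependence of CCM benefit enters through `mu_max`.
* Chemistry is fixed at 25 °C freshwater values; no alkalinity or ionic
  strength corrections, no CO₃²⁻ or carbamate.
* The energy cost of uptake is proxied by the uptake flux $J_\chi$ itself;
  no ATP stoichiometry is asserted.
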