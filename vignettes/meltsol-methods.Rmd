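---
title: "From fast-scanning calorimetry to aqueous amino-acid solubility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From fast-scanning calorimetry to aqueous amino-acid solubility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Amino acids decompose below their melting points, so their melting
temperature $T_\mathrm{fus}$ and molar enthalpy of fusion
$\Delta_\mathrm{fus}H$ cannot be measured by conventional calorimetry. Yet
these two properties are exactly what a thermodynamic solubility prediction
needs: for a pure solid in equilibrium with a saturated solution, neglecting
the heat-capacity difference between solid and subcooled liquid,

$$x^{L,\mathrm{sat}}\,\gamma^\mathrm{sat}
  = \exp\!\left[-\frac{\Delta_\mathrm{fus}H}{R}
  \left(\frac{1}{T}-\frac{1}{T_\mathrm{fus}}\right)\right],$$

with $R = 8.314\ \mathrm{J\,mol^{-1}K^{-1}}$. Fast scanning calorimetry
(FSC) heats sub-100-ng samples at $10^3$–$10^4$ K/s, outrunning
decomposition, and so makes the left-hand inputs measurable. `meltsol`
implements both halves of this chain — the FSC data reduction and the
equation-of-state solubility machinery — plus seeded synthetic-data
generators so every stage can be tested against planted ground truth.

## The equation of state

Activity coefficients are computed from PC-SAFT on the mole-fraction scale
with a pure-liquid reference,
$\gamma_i = \varphi_i(T,P,x)/\varphi_{0i}(T,P)$, where $\varphi_{0i}$ is the
fugacity coefficient of the pure — for a solid solute, hypothetical
subcooled — liquid at the same temperature and pressure. The residual
Helmholtz energy is the standard three-term sum

$$\tilde a^\mathrm{res} = \tilde a^\mathrm{hc} + \tilde a^\mathrm{disp}
  + \tilde a^\mathrm{assoc},$$

with the Boublík–Mansoori hard-sphere mixture term and chain correction,
the two universal seventh-order dispersion power series in packing fraction,
and the Wertheim first-order association term. Water, glycine and
l-alanine all carry a 2B association scheme (one donor and one acceptor
site per molecule). Water uses a three-term exponential
temperature-dependent segment diameter; that diameter enters every packing
moment, radial-distribution contact value and association strength
consistently. Cross interactions use the Berthelot–Lorentz rules
$\sigma_{ij}=(\sigma_i+\sigma_j)/2$ and
$u_{ij}=(1-k_{ij})\sqrt{u_i u_j}$, with $k_{ij}(T)$ linear in temperature
for the l-alanine/water pair. Cross association uses the arithmetic mean of
the association energies and the geometric mean of the association volumes
scaled by the usual cubed ratio of geometric to arithmetic mean segment
diameters (Wolbach–Sandler). These are the standard published conventions;
the source data for the parameter table do not state any deviation from
them, and the packaged battery of limits and finite-difference oracles pins
the implementation down against closed forms (Carnahan–Starling, the
one-component 2B site fraction) and against published pure-fluid benchmark
results for non-associating reference substances.

### Numerics

* **Association site balances.** For 2B schemes with symmetric
  donor/acceptor strengths the two site fractions per component are equal,
  so one unknown per associating component remains:
  $X_i = (1+\rho\sum_j x_j X_j \Delta_{ij})^{-1}$. These are solved by
  damped successive substitution (damping 0.5) followed by a Newton polish
  on the full balance system, to a residual of $10^{-13}$; a test compares
  the reduced solution against a brute-force solve of the unreduced
  four-site system.
* **Pressure.** The compressibility factor uses analytic packing-fraction
  derivatives for all three contributions; for the association part the
  stationarity of the Helmholtz energy with respect to the site fractions
  makes the derivative at frozen $X$ exact. Central-finite-difference
  oracles assert agreement to $10^{-8}$.
* **Chemical potentials.** Composition partials of
  $\tilde a^\mathrm{res}(T,\rho,x)$ are taken by complex-step
  differentiation (step $10^{-200}$), which is exact to machine precision
  and is verified against real central differences of the total residual
  Helmholtz energy at constant $T,V$. The fugacity coefficients follow as
  $\ln\varphi_i = \mu_i^\mathrm{res}/RT - \ln Z$.
* **Density.** The packing-fraction axis $(10^{-10}, 0.7404)$ is scanned
  for sign changes of $P(\eta)-P$; each bracket is refined by Brent's
  method and a Newton polish drives the relative pressure residual to
  $10^{-12}$. The machine-level residual matters: osmotic coefficients at
  high dilution are differences of nearly equal fugacity coefficients, and
  a looser root would visibly corrupt the $\Phi \to 1$ limit. The liquid
  phase takes the highest-density root, the vapor the lowest; with multiple
  roots the lower residual-Gibbs-energy root is flagged stable. The
  subcooled pure-liquid reference for a solute below its melting point is
  deliberately the highest-density root — the saturation relation above
  presumes exactly this hypothetical-liquid construction.
* **Saturation.** `predict_solubility()` iterates
  $x \leftarrow x_\mathrm{ideal}/\gamma(x)$ with damping 0.5 from the ideal
  solubility and finishes with a bracketed root polish; `fit_hfus()` wraps
  it in a one-dimensional root solve over a 5–50 kJ/mol band, and
  `fit_kij()` minimises the sum of squared osmotic-coefficient residuals
  over the 298.15 K intercept only, holding any literature temperature
  slope fixed (re-fitting the slope to solubility data would destroy the
  predictive character of the chain, so it is deliberately out of scope).

Pressure is fixed at 101325 Pa in all worked examples; molar masses are
18.015 (water), 75.1 (glycine) and 89.1 (l-alanine) g/mol, and molality
converts to mole fraction as $x = m/(m + 1000/M_w)$.

## FSC reduction

A heating scan is reduced in four steps.

1. **Sample mass** (`determine_sample_mass()`): the ratio of measured
   sample heat capacity to a literature specific heat capacity, averaged
   over a pre-melting window; heating and cooling curves must agree (mass
   loss guard), and the mass carries an 11% relative uncertainty, the
   dominant systematic of chip calorimetry. The packaged solid-state
   $c_p(T)$ table is a synthetic stand-in with realistic magnitudes
   (≈1.3–1.4 J/g/K near ambient, rising with $T$) — replace it with the
   laboratory's own calibration for real work.
2. **Peak detection** (`detect_melting_peak()`): a linear baseline is
   fitted over windows 20 K wide separated by 5 K from the peak extent;
   the onset is the intersection of that baseline with the tangent at the
   leading-edge inflection point, computed from a local cubic fit (exact
   for a straight edge, unbiased to high order for curved ones); the
   enthalpy is the time integral of the baseline-subtracted heat flow
   between the 0.5%-of-height crossings. The onset is invariant to
   baseline offset and to uniform unit rescaling.
3. **Zero-rate extrapolation** (`extrapolate_zero_rate()`): apparent onsets
   shift with heating rate through thermal lag and superheating; an
   ordinary least-squares line in $\beta$ gives the thermodynamic melting
   temperature as its intercept. No separate per-scan lag model is applied
   — the extrapolation absorbs rate-proportional lag by construction. The
   uncertainty combines the t-scaled intercept standard error with a
   temperature-calibration term (default 5 K) in quadrature.
4. **Molar enthalpy** (`molar_fusion_enthalpy()`): peak areas grow linearly
   with sample mass irrespective of rate, so the through-origin regression
   slope is the specific fusion enthalpy; times molar mass and with the
   11% mass uncertainty added in quadrature (coverage factor 2), this
   yields $\Delta_\mathrm{fus}H$, and $\Delta_\mathrm{fus}S =
   \Delta_\mathrm{fus}H/T_\mathrm{fus}$ with first-order propagation. The
   expanded-uncertainty convention approximates the full laboratory
   uncertainty budget by standard-error propagation; it is an
   approximation, stated as such.

## What the synthetic generator emulates — and what it does not

`simulate_thermogram_set()` produces scan sets with a planted zero-rate
onset, a rate-proportional apparent-onset shift (default
$5\times10^{-4}$ K per K/s, i.e. a few kelvin across 1000–10000 K/s, small
against the default 3 K onset scatter), mass-proportional peak areas, a
mildly sloped sensor baseline, additive Gaussian noise, and reported sample
masses perturbed by the 11% mass uncertainty. Two leading-edge shapes
(linear and Gaussian, both calibrated so the tangent construction recovers
the planted onset) guard the reduction against shape dependence. The
default campaign is 45 scans at 9 rates spanning 1000–10000 K/s with
masses of 40–100 ng and specific enthalpies of a few hundred J/g —
the scale of a real FSC melting study of this kind.

The generator does **not** simulate heat transfer in the chip sensor,
curvature of thermal lag with rate, decomposition or evaporation kinetics,
or cold-crystallization signatures. Noise is the only deviation from the
forward model, so recovery tests are well-posed: passing them shows the
reduction inverts its own forward model within stated uncertainties, not
that it is robust to every instrumental artifact of real thermograms.
Likewise `simulate_osmotic_table()` and `simulate_solubility_table()`
apply multiplicative noise to the exact forward model (solubility scatter
is capped by the ~3% typical of experimental data), so parameter-recovery
tests validate the fitting machinery, not the model's adequacy for real
mixtures.

## Design choices where the design was open

* **Association conventions.** The source table for the parameters does not
  restate the cross-association rules; the standard Wolbach–Sandler rules
  are used. The alanine activity coefficient at saturation is extremely
  sensitive to the cross-association energy (about 0.6% per kelvin of
  $\varepsilon^{A_iB_j}/k_B$), so small convention differences between
  implementations move it by a few percent — the packaged value computed
  here (0.236 at $x = 0.03188$, 298.15 K) sits about 2% below the value
  implied by the fitted fusion enthalpy and the saturation relation
  (0.240), while the independently reported equation-of-state value (0.244)
  is itself about 1.7% inconsistent with that relation. The fitted
  enthalpy, which is what propagates into solubility predictions, agrees
  with the reported one to 0.4%.
* **Degenerate inputs.** Flat thermograms raise a no-peak error (with an
  absolute floor so noise-free constants are rejected too); two comparable
  peaks raise an ambiguity error listing candidates; equal masses make the
  enthalpy regression ill-conditioned and are rejected; onsets at fewer
  than three rates cannot be extrapolated.
* **Seeds.** Every generator is a pure function of its integer seed
  (`withr::with_seed`), so campaigns are bit-reproducible and the
  command-runner's outputs are byte-identical across re-runs.
* **Problem sizes.** The packaged tests run the full Monte-Carlo coverage
  study at 100 replicates of the 45-scan campaign, the interaction-
  parameter recovery at 20 noisy replicates of 6-point isotherms, and the
  enthalpy-fit recovery across 10 planted melting-property pairs; these
  sizes give stable pass/fail behaviour for the stated coverage targets.

## Known limitations

* No polar, quadrupolar or electrolyte terms; no mixed solvents; no
  glass-transition or cold-crystallization analysis; no decomposition
  kinetics; no vapor–liquid flash beyond the density/fugacity primitives.
* The saturation relation omits the $\Delta c_p$ correction by
  construction; predictions far below the melting point inherit whatever
  error that approximation carries.
* Fitted melting properties from solubility data are famously
  model-dependent (published values for these two amino acids span
  hundreds of kelvin and an order of magnitude in enthalpy; see the
  packaged literature comparison table `table3_literature_melting.csv`) —
  which is precisely why the measured-property route implemented here is
  preferable.

## A worked example

```{r, eval = FALSE}
library(meltsol)
params <- load_parameter_set(meltsol_example("table1.yaml"))

# melting-property route to the activity coefficient of glycine
gly <- melting_properties("glycine", T_fus = 569, dH_fus = 21000)
gamma_from_melting(0.05724, 298.15, gly)        # 0.3097

# full equation-of-state route for l-alanine at its solubility
activity_coefficient(params, "l-alanine", x = 0.03188, T = 298.15)  # 0.2357

# fit the fusion enthalpy to the experimental solubility at 298.15 K
fit_hfus(params, "l-alanine", target_molality = 1.828,
         T = 298.15, T_fus = 608)               # 23.79 kJ/mol

# reduce a synthetic FSC campaign
scans <- simulate_thermogram_set(scan_protocol(seed = 42))
reduce_fsc(scans, molar_mass = 89.1, substance = "l-alanine")$melting
```
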