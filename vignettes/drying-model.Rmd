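---
title: "A coupled heat-mass model of hot-air and RF-assisted drying of fruit slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled heat-mass model of hot-air and RF-assisted drying of fruit slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The physical problem

`rfdry` simulates the drying of a thin cylindrical fruit (winter-jujube)
slice — 30 mm diameter, 8 mm thick, 79.6% initial wet-basis moisture —
exposed to hot air at 60 °C and 2.5 m/s, optionally supplemented by a
27.12 MHz radio-frequency (RF) field between parallel plate electrodes
110 mm apart. Hot air removes surface moisture efficiently but heats the
interior slowly by conduction; RF deposits power volumetrically, raising the
core temperature and accelerating the migration of interior moisture. The
package exists to study *when* in a drying schedule RF is best applied: the
4.5 h process is divided into three equal stages and RF is switched on in
the early (E-HA+RF), middle (M-HA+RF) or late (L-HA+RF) stage, or not at
all (HA).

## Governing equations

Inside the slice the model couples conduction with Fickian moisture
diffusion on an axisymmetric (r, z) cross-section:

- energy: `rho_s Cp dT/dt = div(k grad T) + Q_rf`
- moisture: `dC/dt = div(D_eff grad C)`

with `C = rho_dm M_db` the liquid-water concentration (kg/m³), `rho_dm` the
(constant, no-shrinkage) dry-matter density. A convective-term artefact
sometimes written inside the energy balance (air viscosity multiplying a
temperature gradient) is dimensionally inconsistent for an intact solid and
is omitted: the interior is conduction plus source.

Boundary conditions follow the one-sided drying configuration of a slice
lying on a tray: the top face exchanges heat convectively and loses moisture
evaporatively, the lateral face exchanges heat only, and the bottom face is
adiabatic and impermeable:

- heat: `-k dT/dn = h_T (T_s - T_air) + h_fg h_m (C_s - C_eq)`
- moisture: `-D_eff dC/dn = h_m (C_s - C_eq)`

`C_eq = rho_dm Me` is the surface concentration in equilibrium with the
drying air (`Me` = 0.05 kg/kg dry basis by default). The latent-heat sink
couples the two equations at the surface; evaporative cooling is what holds
the early-drying temperature well below the air temperature.

### Material properties

Four fitted regressions (T in °C, W the wet-basis moisture *fraction*)
drive all coupling:

| quantity | regression | units |
|---|---|---|
| specific heat | `0.043 T + 1.047 W − 1.333` | kJ kg⁻¹ K⁻¹ |
| thermal conductivity | `0.008 T + 0.675 W − 0.261` | W m⁻¹ K⁻¹ |
| dielectric constant ε′ | `34.519 W + 0.072 T + 46.022` | — |
| loss factor ε″ | `319.028 W + 1.150 T + 3.786 W T + 46.952` | — |

The linear Cp and k fits go negative far below the measured moisture range,
so evaluations are clamped at floors (0.85 kJ kg⁻¹ K⁻¹, 0.05 W m⁻¹ K⁻¹)
typical of dry plant solids; inside the solver, inputs outside the fitted
(T, W) window are extrapolated as constants rather than erroring, since
brief excursions (evaporative cooling below 15 °C, RF heating above 100 °C)
are expected in transients. W is interpreted as a fraction (0–1): with that
reading ε′ exceeds 70 at high moisture, as observed for near-saturated
tissue.

### The RF field and heat source

At 27.12 MHz and centimetre scales the field is quasi-static: the complex
potential solves `div((sigma + j omega eps0 eps*) grad V) = 0` with the top
plate energised and the bottom grounded. The volumetric source is
`Q_rf = 2 pi f eps0 eps'' |E|²` (RMS convention). Two solvers are provided:

- **layered** (default): the plate/air/sample stack is a series capacitor;
  `E_i = V / (eps*_i · sum_j d_j / eps*_j)` per layer. The sample's
  volume-averaged ε* defines the stack; the local ε″ then scales the nodal
  power deposition. This matches the single-slice focus of the study design
  and is essentially free to evaluate.
- **2-D**: a finite-volume complex Laplace solve on the full (r, z) gap
  cross-section, retaining fringing at the slice edge. Face admittivities
  are area-weighted, which makes horizontally stratified media exact; the
  solver is validated against the layered closed form and by the identity
  between volume-integrated dissipation and plate-current complex power.

Because ε* drifts slowly with T and W, the field is re-solved only when the
temperature or moisture field has moved by more than 0.5 °C or 0.05 kg/kg
since the last solve (configurable).

The electrode voltage is the one genuinely free electrical parameter (plate
voltage under load is rarely known in RF dryers); the default 11 kV gives
sample fields of a few hundred V/m and stage-average volumetric powers of
order 10⁴–10⁵ W/m³, placing RF-stage temperatures in the 57–75 °C band
reported for this process. `calibrate_voltage()` reproduces the
trial-and-error adjustment against a measured record as a bracketed
scalar minimisation.

### Drying kinetics (Dincer model)

From a measured or simulated curve of dry-basis moisture `M_db(t)` the
package estimates transfer parameters through the exponential lag model
`MR = Lf exp(−S t)` fitted log-linearly, followed by the closed-form chain:

- `Bi = 1.3 ln Lf / (0.2533 − ln Lf)` (inverse of the lag-factor relation),
- `mu1 = atan(0.640443 Bi + 0.380397)`, or π/2 for Bi ≥ 100,
- `D = S L² / mu1²`, `hm = Bi D / L`.

The characteristic length deserves care: for one-sided drying (evaporation
from the top face only) the correct `L` is the **full** slice thickness,
because a one-sided slab is the half-domain of a symmetric slab of double
thickness. The slope method (`eff_diffusivity_slope()`) uses the first-term
slab series `MR = (8/pi²) exp(−pi² D t / (4 L²))` on a user-selected
falling-rate window. The Prandtl exponent in the flat-plate correlation
`Nu = 0.664 Re^0.5 Pr^0.33` is implemented exactly as printed (0.33, not
1/3).

A caution that the round-trip tests make precise: the chain is exact when
the curve really is a single exponential mode. Applied to a curve with an
early multi-mode transient or a drifting (temperature-dependent)
diffusivity — including this package's own simulated output — the fitted
lag factor is pulled toward 1, which the Bi-inversion reads as a small Biot
number and compensates with a large apparent D. The estimates remain useful
as lumped engineering parameters of the fitted window, but they are not the
PDE's local coefficients; choose the fitting window accordingly.

## Numerical scheme

Cell-centred finite volumes on the axisymmetric cross-section (default
9 × 8 cells over 15 mm × 8 mm; ring volumes sum to the cylinder volume
exactly), backward-Euler time stepping at `dt = 1 s`, and Picard iteration
over the property nonlinearity: each iteration re-evaluates Cp, k, D_eff
(and, on its cadence, the RF field) at the current iterate, then takes one
implicit heat step and one implicit mass step. Convergence is declared when
successive iterates move by less than 10⁻³ °C and 10⁻⁶ relative moisture —
deliberately much stricter than loose engineering tolerances, because the
conservation audits below are only meaningful when the linear systems are
solved essentially exactly. At `dt = 1 s` two iterations per step are
typical.

Boundary faces fold the half-cell conduction resistance into the film
coefficient (`U = 1/(1/h + d/2k)`), which keeps the Robin condition
second-order accurate; interior face conductivities and diffusivities are
harmonic means. Because the scheme is conservative by construction, every
run accumulates exact discrete budgets: stored-energy change versus
convective input, evaporative sink and RF input; stored-moisture change
versus boundary outflux. Residuals are reported in `result$audit` and close
to round-off in practice — the audit tests at 0.5%/1% are deliberately
generous bounds on that construction.

Degenerate inputs are handled explicitly: all-zero conductivity is a
singular-system error, negative diffusivity errors, schedules must tile the
time axis exactly, zero-duration runs return the initial state, and a state
at `(T_air, C_eq)` is an exact fixed point reached in one Picard iteration.

## Default parameters and how they were chosen

Geometry, air state, frequency, gap, stage structure, time step and the
initial condition (22 °C, 79.6% wb) are the study conditions themselves.
Three quantities are not published for this process and were fixed once, on
physical grounds, when the model was assembled:

- `D_ref = 6.5e-9 m²/s` at 60 °C and `h_m = 3e-6 m/s`. These give a mass
  Biot number of ~3.7 and place the hot-air run's crossing of the
  1.0 kg/kg dry-basis target in the late third of the 4.5 h window —
  matching the account that hot air alone barely reaches the target while
  mid/late-stage RF brings moisture down to it quickly. (Had the defaults
  dried faster, the late-RF scenario could not possibly beat hot air to the
  target, since the crossing would predate its RF stage.)
- `V_top = 11 kV`, as discussed above.

The moisture diffusivity follows an Arrhenius law
`D(T) = D_ref exp(−Ea/R (1/T − 1/T_ref))` with `Ea = 30 kJ/mol`, a typical
activation energy for moisture transport in fruit tissue. This temperature
dependence is **on by default**: it is the physical channel by which RF
heating accelerates drying. With a strictly constant D the mass equation
would decouple from temperature entirely and all four schedules would
produce identical moisture curves — a defensible simplification for
isothermal kinetics fitting, but not for comparing heating schedules. A
constant-D run is available via `transport$arrhenius = FALSE`.

## What the synthetic fixtures do and do not show

`make_fixture()` produces pseudo-experimental records: a simulation
resampled at the 30-min weighing cadence with seeded Gaussian noise
(standard deviation a chosen fraction of each series' range). They exercise
the calibration and goodness-of-fit machinery (`compare_series()` reports
R², max/min absolute difference, RMSE) deterministically and at known
ground truth. They inherit the model's own physics — no shrinkage, Fickian
transport, one-sided evaporation, a single slice — so passing tests against
them demonstrates internal consistency and correct inversion, not agreement
with real dryers. Validation against independent physics rests on the
analytic oracles: the 20-term transient conduction series, the first-term
diffusion decay rate, the layered-capacitor field, and the discrete
conservation identities.

## Problem sizes used in the shipped tests

The test-suite runs use the default 9 × 8 grid for full-length (16 200 s)
scenario runs; oracle comparisons refine the vertical direction to 40 cells
and shrink the time step to 0.25–0.5 s; calibration property tests use a
4 × 4 grid, 15 s steps and a 900 s horizon, which is ample because voltage
recovery is a property of the monotone field-power map, not of resolution.
Monte-Carlo properties (noisy kinetics recovery, noisy calibration,
fixture R²) use 20–100 seeds.

## Known limitations

- No shrinkage, porosity evolution or case hardening; properties depend on
  (T, W) only.
- Liquid-diffusion transport: no internal vapour pressure-gradient term,
  which real RF drying can induce at high power.
- The layered field mode ignores edge fringing (retained only in the 2-D
  solver) and the polypropylene tray (thin, low-loss).
- Single slice; no load interaction or cavity detuning at high fill.
- The energy audit treats the evaporation enthalpy at the surface cell
  temperature; sub-cell surface temperature structure is not resolved.
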