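---
title: "Models and methods behind pbrsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pbrsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbrsim)
```

`pbrsim` simulates an outdoor fence-type tubular photobioreactor: a
transparent tubular loop (solar receiver) closed on a bubble column that
degasses, mixes and thermally conditions the culture. This vignette
documents the models, the numerical scheme, the parameters that matter and
why their defaults are what they are, and what the simulator does *not*
capture.

## Plant structure and state

The default geometry is a 400 m tube of 0.09 m diameter plus a 3.5 m x
0.4 m column (90 % liquid, 10 % gas holdup). The loop is treated as a
plug-flow reactor discretised into `n_elements = 50` perfectly mixed
elements (8 m each at the defaults); the column is perfectly mixed in both
phases, so its outflow composition equals its bulk composition. Each
liquid compartment carries biomass (g/m^3), dissolved O2 and total
inorganic carbon C_T (mol/m^3), and a temperature; the column gas phase
carries O2 and CO2 mole fractions.

Fifty elements resolve the ~444 s transit of the loop into ~9 s residence
steps, which is enough that doubling the element count moves the
end-of-day pH and biomass by well under 1 % (checked in the test suite);
`n_elements = 1` degenerates the loop into a second mixed tank and is
supported for quick qualitative runs.

## Solar forcing

Synthetic irradiance uses standard solar geometry: Cooper's declination
formula, the hour-angle expression for cos(zenith), the extraterrestrial
irradiance with the 1367 W/m^2 solar constant and the 3.3 % orbital
eccentricity correction, and a *clearness index* k_t in [0, 1] that scales
extraterrestrial to ground-level global irradiance. k_t is applied
instantaneously and held fixed for a run (a whole simulated day is "a
clear day" at k_t = 0.8 or "overcast" near 0); this makes the daily
irradiance integral exactly linear in k_t, a convenient experimental
dial. The direct/diffuse split uses the Erbs piecewise-polynomial
diffuse-fraction correlation; note the quartic branch has its minimum near
k_t = 0.73, so the diffuse fraction is not strictly decreasing all the way
to the clear-sky branch.

Two deliberate simplifications, flagged here because they matter for
comparing against measured data: solar time is used directly (no equation
of time, no longitude correction -- longitude is accepted in the
configuration but unused), and only horizontal irradiance is modelled (no
tilted-surface transposition). Recorded profiles can be loaded from CSV
(`load_profile()`); the clearness index is then back-computed per sample
(capped at 1) only to drive the Erbs split. Ambient temperature defaults
to a sinusoid (mean 22 C, amplitude 6 C, peak at 15:00 solar time), a
stand-in for the measured ambient series a real campaign would supply.

## Growth kinetics and light

Light inside the culture is the Beer-Lambert *average* irradiance over the
tube diameter p: I_av = I_0 (1 - exp(-K_a C_b p)) / (K_a C_b p), with the
transparent-culture limit handled analytically. Photosynthetic O2
evolution is a Hill light response times a clipped dissolved-oxygen
inhibition factor:

R = C_b r_max I^n / (I_half^n + I^n) * max(0, 1 - (dO2 / dO2_inh)^m) - C_b r_resp

Biomass grows in proportion to the *gross* light-driven term through a
yield Y (g biomass per mol O2); respiration always consumes O2 and
releases CO2, but erodes biomass only behind an off-by-default flag, so a
default night leaves biomass flat. Carbon fixation couples to the O2 rate
through the photosynthetic quotient PQ (mol O2 per mol CO2, default 1).

### Calibration constants

The kinetic and carbonate defaults are **calibration constants of this
simulator**, chosen once so that the shipped one-day reference experiment
reproduces the plant's documented behaviour, and frozen; they are not
species measurements. The load-bearing ones:

| parameter | default | units | role |
|---|---|---|---|
| `r_o2_max` | 2.14e-7 | mol O2 g^-1 s^-1 | scale of daytime fixation |
| `i_half` | 280 | W/m^2 | light half-saturation |
| `hill_n` | 2 | -- | light response steepness |
| `o2_inhibition_conc` | 0.95 | mol/m^3 | full O2 inhibition point |
| `extinction_coeff` | 0.06 | m^2/g | culture optical density |
| `yield_x_per_o2` | 26 | g/mol | ~46 % carbon biomass at PQ = 1 |
| `alkalinity_mol_m3` | 13 | mol/m^3 | bicarbonate-rich medium |
| `kla_co2` | 0.021 | 1/s | column CO2 stripping |
| `co2_absorption_eff` | 0.9 | -- | injected CO2 actually dissolved |

The chemistry numbers come from the steady-state carbon balance: at a
constant injection flow the plateau CO2(aq) is
c = c*_air + (injection - fixation) / k_e, where k_e is the *gas-side
limited* effective stripping conductance (see below), and pH follows from
c and the alkalinity. Matching two plateau pairs (high flow by day, low
flow into the night) pins alkalinity and k_La CO2; `r_o2_max` then sets a
daytime fixation small enough (~10 % of the high injection rate) that the
daytime plateau is flat despite the moving sun. `i_half = 280 W/m^2`
keeps the light response unsaturated at midday average irradiances
(~400 W/m^2), so O2 production tracks the sun and the dissolved-O2 maximum
falls at solar noon rather than drifting into the afternoon with biomass
growth.

## Carbonate system and pH

pH solves the charge balance Alk = [HCO3-] + 2[CO3 2-] + [OH-] - [H+]
with carbonate fractions the usual functions of [H+], K1, K2 (pK 6.35 and
10.33 on the mol/L scale, converted internally to mol/m^3). The solver is
bisection bracketed on pH in [2, 12] (60 halvings, i.e. machine precision
in pH; residuals ~1e-12 mol/m^3); inputs whose solution falls outside the
bracket raise a configuration error rather than extrapolating. The
engine's inner loop instead warm-starts a guarded Newton iteration from
the previous step's [H+] (two iterations per 1 s step track the rigorous
solver to ~1e-6 pH, verified against it in the tests, with automatic
fallback to bisection if Newton leaves the bracket). Alkalinity is fixed
over a run: CO2 injection changes C_T, not Alk, which is the standard
closure when only CO2 crosses the gas-liquid boundary.

## Gas phase and CO2 accounting

The column gas is a constant molar holdup with a quasi-steady vent:
F_out = F_in + net transfer, so mole fractions stay bounded and the vented
composition equals the holdup composition. This coupling matters: CO2
stripping is *gas-side limited*. With k_La V ~ 8e-3 m^3/s and
F_air/H_CO2 ~ 1.6e-3 m^3/s, the effective conductance
k_e = k_La V / (1 + k_La V H / F) is ~6x smaller than k_La V alone -- the
vent simply cannot carry CO2 away faster than F y_CO2. Ignoring this makes
it impossible to reconcile the two reference plateaus with any positive
fixation rate. Injected CO2 is split into a dissolved fraction (90 % by
default) entering loop element 1 and reported losses; the loop itself has
no gas exchange (closed tube), which is why photosynthetic O2 accumulates
along it until the airlift strips it.

## Thermal model

The volume-element method: one first-law ODE per lumped volume,

dT/dt = [m_dot c_p (T_up - T) + U_wall A_out (T_amb - T) + alpha A_proj G - Q_hx] / (rho V c_p)

with the chain column -> element 1 -> ... -> element N -> column. The
plant's empirical internal/external convection correlations are collapsed
into one combined wall conductance U_wall (15 W m^-2 K^-1 per unit outer
area), and long-wave sky radiation is omitted; the structure (lumped
volumes, first-law balance, low computational demand) is the point, not
coefficient-level fidelity. Radiation is captured on the projected area
(diameter x length) with absorptivity 0.35; the heat exchanger in the
column uses an effectiveness-NTU model (UA = 500 W/K) on the cooling-water
flow. The thermal grid defaults to co-location with the mass-balance
elements. Temperature does not modulate the growth kinetics by default --
the thermal state is an output (and a controlled variable), decoupled from
the biology unless the user wires it otherwise.

## Control loops

Three loops: CO2 valve vs pH (measured at the pre-injection sensor, the
one the valve directly acts on; the column-entry and mid-loop sensors are
logged), pump vs culture velocity, cooling-water valve vs column
temperature. Each loop runs in one of four modes:

* **manual** -- fixed or scheduled value of the manipulated variable;
* **on/off** -- relay with deadband;
* **pi_time** -- positional discrete PI, u = sat(k_p e + (k_p/t_i) I),
  sampled every t_s, conditional-integration anti-windup plus a hard
  integrator clamp |I| <= (u_max - u_min) t_i / |k_p|;
* **pi_event** -- symmetric send-on-delta (SSOD) PI: the *measurement* is
  transmitted only when it crosses the next quantisation level
  (setpoint + k delta), and the PI law runs on the held quantised error.
  Inside the central band the quantised error is zero, so the command
  freezes and the loop is silent.

An earlier realisation that updated the PI only at event instants (dumping
the integral accumulated over the whole inter-event gap in one step)
produced large quantisation limit cycles and was discarded; running the
PI continuously on the held quantised error is the standard SSOD
architecture and is what the event-count economy and delta -> 0
convergence tests exercise.

Actuators are identified first-order lags (CO2 valve gain 5 L/min, tau
2 s; pump 1.8 m/s, tau 5 s; cooling valve 0.5 kg/s, tau 3 s) advanced with
the exact exponential update, so they are unconditionally stable.

### pH-loop tuning

The shipped tuning (k_p = -1.6 per pH unit, t_i = 900 s, t_s = 1800 s,
delta = 0.025 pH) is itself a calibration choice. The pH loop's dominant
dynamics are the C_T pool turnover (~35 min) plus the ~7 min loop
transport delay. Sampling at t_s = 1800 s -- a defensible period for so
slow a chemical loop -- adds enough effective delay that the time-based
loop is distinctly underdamped: it rings for a few hours before settling.
The event-based loop with the *same* k_p and t_i reacts at threshold
crossings without waiting for a sampling instant, stays well damped, and
goes quiet once inside its band; that contrast (hours of settling-time
difference at identical tuning) is the pedagogical point of the
event-based mode. delta is 0.025 pH rather than the half-band 0.05
because an SSOD loop generically cycles within about +-delta of the
setpoint; with delta equal to the settling band the loop could graze the
band forever, while delta at half the band keeps the quantisation cycle
strictly inside it.

## Numerical scheme

Operator splitting per base step (default dt = 1 s), in this order:
controllers (at their sampling instants or on events) -> actuators ->
reaction and gas-liquid transfer (explicit, from the pre-step state) ->
CO2 injection -> upwind advection -> thermal update -> harvest events.
Controllers act before the plant update, matching sampled-data reality.

* **Advection** is first-order upwind with conservative pairing (the
  column sees exactly the flux the loop loses), sub-stepped whenever the
  CFL number v dt / dx exceeds 1. At the defaults CFL = 0.11.
* **Thermal** updates sub-step to stay within half the smallest of the
  advective and wall-loss time constants, and abort with a step-size error
  if any volume would move more than 5 K in one sub-step.
* **Gas phase** time constants (~30 s holdup turnover) and actuator lags
  are comfortably above dt = 1 s.
* Negative concentrations abort the run with the offending time and step
  (they indicate a dt too large for the configured rates).
* Everything is deterministic: the only RNG in the package is the seeded
  noise of the fixture generator, so identical configurations produce
  byte-identical output files.

Halving dt moves the end-of-day pH, biomass and temperature by well under
0.5 % at the defaults (verified in the suite). One simulated day at dt =
1 s, N = 50 takes roughly 15-25 s single-threaded; the test suite runs its
reference days once and caches them.

Conservation audits are first-class outputs: every run accumulates its
source/sink integrals (injection, transfer, vent, fixation, respiration,
harvest) alongside the state, and `check_audits()` closes the carbon,
oxygen (liquid and gas) and biomass books, typically to ~1e-12 relative.

## Harvesting

Ideal and instantaneous: at a scheduled time a fraction f of the biomass
is removed from *all* liquid compartments simultaneously and replaced by
fresh medium at constant volume (biomass scaled by 1 - f, other species
diluted toward the medium composition -- C_T equilibrated at pH 8,
air-saturated O2, no thermal shock). The filter/recycle hardware of a
real harvest line is not resolved.

## What the synthetic conditions do and do not show

The default configuration *is* the reference study condition: the 400 m
plant at 36.8 N, midsummer day 172, k_t = 0.8, 0.9 m/s, 80 L/min air,
initial biomass 400 g/m^3 at pH 8. Passing tests under these conditions
show the coupled model reproduces the documented plateau chemistry,
daily patterns and control contrasts of that plant; they do not show
species-level kinetic fidelity (the kinetics are calibration constants),
nor robustness to weather variability (k_t is fixed per run), nor
validity of the thermal coefficients (collapsed into U_wall). Known
limitations, deliberate: no nutrient (N/P) limitation, no
photoacclimation or shear damage, no tilted-surface radiation, no
within-run clearness variation, no temperature-kinetics coupling by
default, and a quasi-steady constant-holdup gas phase rather than a
sealed-column pressure balance.
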