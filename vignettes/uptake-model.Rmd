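---
title: "Mechanistic soil-root pesticide uptake: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic soil-root pesticide uptake: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizofate)
```

## The problem

Regulatory pesticide-fate models treat root uptake as a purely advective
process: a fixed fraction of the dissolved compound is carried into the
root with the transpiration stream. Real uptake of neutral organic
compounds has a second, diffusive pathway across the root cell
membranes, driven by the concentration difference between the soil
solution at the root surface and the solution inside the root, and rated
by a membrane permeability that depends strongly on the compound's
lipophilicity. Whether the two descriptions agree depends on how water
uptake and solute concentration are distributed in space — which is why
this package resolves both on an explicit 3D root architecture embedded
in a 3D soil grid.

`rhizofate` couples four components:

1. **Soil water flow** — the Richards equation on a structured grid with
   layered van Genuchten-Mualem properties.
2. **Root hydraulics** — a Doussan-type network model on connected root
   segments: radial flow $J_{w,r} = L_r (h_S - h_x)$ into each segment
   and axial xylem flow driven by total water potential through the
   axial conductance $K_x$.
3. **Soil solute transport and fate** — finite-volume
   advection-diffusion with linear equilibrium sorption and first-order
   degradation modified by moisture, temperature and depth.
4. **Root solute uptake and transport** — a single-compartment
   (Trapp-style) segment model,
   $S_R = \frac{A_R}{V_R}\left(P\,(C_{S,l} - C_{R,l}) +
   \varepsilon J_{w,r} C\right)$, with convective transport of the root
   solution to the collar, where arriving mass is booked as translocated
   to the shoot.

The headline diagnostics are the transpiration stream concentration
factor, $\mathrm{TSCF} = (m_{collar}/T_{act})/\bar C_{S,l}$, and the
plant uptake factor, $\mathrm{PUF} = (m_{upt}/T_{act})/\bar C_{S,l}$,
computed per day with $\bar C_{S,l}$ the water-volume-weighted mean
dissolved concentration from the surface down to the day's rooting
depth. The standard uptake fraction (SUF) — each segment's share of
uptake under a uniform soil water potential — summarises the hydraulic
architecture alone.

## Uptake parameters

* $\varepsilon \in [0,1]$ — the advective uptake fraction
  ($1-\sigma$ with $\sigma$ the reflection coefficient of the root's
  Casparian barrier). The regulatory tier-1 default is 0.5; `epsilon = 1`
  means the membrane does not reject the compound at all.
* $P$ (cm/d) — the overall root permeability of the diffusive pathway.
  It can be given directly or derived from lipophilicity with the
  two-resistance relation $\log_{10} P_M = 1.20\,\log K_{OW} - 7.50$
  ($P_M$ in m/s) in series with the cell-wall permeability
  $P_W = 2.5\times10^{-4}$ m/s:
  $P = (1/P_W + 1/P_M)^{-1}$.

```{r}
permeability_from_logkow(1.41) # cm/d, the shipped dummy compound
```

The shipped test compound (`dummy_substance_b()`) is a FOCUS-style
readily degradable, weakly sorbing, marginally volatile dummy substance:
half-life 20 d at reference conditions, $K_D = 0.2$ cm$^3$/g, and a
logKow of 1.41 chosen so that the two-resistance relation evaluates to
the moderately high permeability of 13.4 cm/d that characterises this
class of compound. Degradation is modified by moisture
($\min(1, (\theta/\theta_{ref})^{0.7})$), temperature (exponential
Arrhenius-type factor normalised to 1 at 20 °C, zero below freezing)
and a piecewise depth factor (1 / 0.5 / 0.3 above 30 / 60 / 100 cm and
0 below), the standard structure of first-tier leaching models. The SI
of published parameterisations was not reproduced here; the layer table
(`hamburg_like_layers()`) is a documented synthetic stand-in for a
sandy-loam-over-sand profile, not a transcription.

## Root architectures

Three sources are supported: RSML files (`read_rsml()`), a single
vertical axis with a linear depth schedule (`generate_single_root()`:
depth $= \min(D_{max}, D_{max}\,t/t_{full})$, by default 100 cm at 89
days after planting), and a seedable stochastic maize-like generator
(`generate_stochastic_root_system()`) with gravitropic crown axes and
two orders of laterals. The generator's defaults were chosen once to
satisfy the structural constraints of a 1D-comparable maize stand:
roughly uniform root length density with depth (each 10-cm bin within
±30 % of the mean), a total density of about 0.1 cm cm$^{-3}$ in a
75 × 15 × 100 cm$^3$ footprint, and the single-root depth schedule.
Axes splay like crown roots (insertion angle up to 45°) before
gravitropism turns them down; this also prevents the physically
implausible situation of an entire root system drawing water from the
single soil cell below the collar. One RNG stream per axis (derived from
the scenario seed) makes the topology independent of iteration order.

The single-root scenario represents the whole uniform root system of a
1D crop model by one effective axis in a 0.9 × 0.9 cm$^2$ column
(1/(0.9 × 0.9) ≈ 1.2 cm cm$^{-3}$). Its radial conductivity
(2 × 10$^{-4}$ cm d$^{-1}$ cm$^{-1}$) and axial conductance
(5 × 10$^{-1}$ cm$^4$ d$^{-1}$ cm$^{-1}$) are uniform, and its radius
(0.003 cm) is an *effective tuning parameter*, not maize anatomy: with
radial conductance $L_r\,2\pi r l$, the hydraulic length
$\sqrt{K_x/(L_r 2\pi r)}$ must be large compared to the 100-cm root for
the standard uptake fraction to be uniform (spread < 5 %), which is the
defining property of this abstraction.

```{r}
rs <- generate_single_root(100, 89, radius = 0.003)
suf <- compute_suf(rs, constant_hydraulics(2e-4, 0.5), t = 120)
(max(suf$suf) - min(suf$suf)) / mean(suf$suf)
```

## Numerical choices

**Richards solver.** Mixed-form modified-Picard iteration (the
mass-conservative formulation), 7-point finite volumes, geometric-mean
face conductivities, laterally periodic boundaries, net-flux top
boundary and prescribed-head bottom boundary. Convergence requires the
water-content increment below $10^{-8}$ and the head increment below
$10^{-5}$ cm; non-convergence halves the step recursively (15 levels
before erroring). Two robustness guards: evaporative demand ramps to
zero as the surface approaches an atmospheric-equilibrium head
($-10^5$ cm), and Picard increments are clamped (1000 cm) with adaptive
under-relaxation on clear oscillation. The linear systems are SPD; on
grids up to 50 000 cells each Picard iteration refactorises (cheap),
larger grids use conjugate gradients preconditioned with a frozen
Cholesky factorisation that is refreshed only when CG convergence
degrades — the system changes little between iterations, and a
factorisation of a 75 × 15 × 145 grid costs seconds.

**Root water uptake coupling.** The xylem network is solved
steady-state each step (no root capacitance) against the soil heads of
the step start, flux-controlled at the collar and re-solved with the
collar head fixed at the critical value (default −15 000 cm) when the
flux-controlled solution falls below it; negative actual transpiration
in that mode (hydraulic lift) is permitted. A segment senses the
length-fraction-weighted mean head of the cells it traverses. Because
the sink is explicit in time, a cell could be over-drained within one
step; uptake per cell is therefore capped at 20 % of the
plant-available water (above the water content at the critical head)
per step, segment fluxes are scaled accordingly and the axial flows are
rebuilt from the scaled radial flows so the network stays exactly
balanced. This brings water stress forward slightly relative to a fully
implicit coupling; it never creates or destroys water.

**Soil solute transport.** First-order upwind advection using the water
step's face fluxes, harmonic-mean impeded diffusion
($D\,\tau\,\theta$), internal CFL sub-stepping (never silently
unstable), exact exponential degradation of the total (dissolved +
sorbed) mass, and the root sink applied to dissolved mass with an
upstream limiter so no cell goes negative. Rain carries no solute and
evaporation leaves solute behind, so the top boundary solute flux is
zero in both directions; the bottom boundary is advective only, with
upward inflow carrying a prescribed boundary concentration. A
finite-volume scheme was chosen over particle tracking for exact local
mass conservation and deterministic, testable ledgers; the governing
conservation equation is unchanged.

**Radial exchange.** Holding the soil concentration fixed over a step
(operator splitting), the segment exchange ODE is linear and is
integrated *analytically* — important because at $P$ = 13.4 cm/d and
fine radii the relaxation rate $2P/r$ reaches thousands per day, which
would force tiny explicit steps. The advected concentration is upwinded
by the sign of $J_{w,r}$: influx carries soil solution, efflux carries
root solution. The uptake law as often printed always carries the soil
concentration, which for efflux moves mass against the water; because
the physical reading is that solute "can be released back into the
soil", upwinding is the default and the printed literal form remains
available (`literal_advective_efflux = TRUE`) for comparison.

**Root axial transport.** Upwind semi-discretisation along the network,
integrated with classical Runge-Kutta sub-steps sized well inside the
CFL limit; collar export and tissue degradation are integrated as
additional state components of the same scheme, so the root ledger
closes to rounding. Axial diffusion is omitted: with $D \approx 1$
cm$^2$/d, $v \approx 1000$ cm/d and $d = 0.1$ cm the within-root Peclet
number is 100 — transport is convection-dominated. Perfect mixing
within a segment is assumed, and newly emerged segments start with zero
solute (the compound is applied to the soil). Reversed collar flow
(downward xylem flow after rain wets the topsoil) carries zero
concentration because no shoot compartment is modelled beyond the
collar accumulator.

**Splitting order.** Per step: (1) alive segments and mapping, (2)
xylem solve with collar switching, (3) Richards step with the water
sink, (4) analytic radial exchange and soil sink, (5) soil transport
and fate, (6) root axial advection and collar accrual, (7) metrics and
ledgers. Steps never straddle forcing-day boundaries; forcings are
piecewise-constant per day. `dt_max` defaults to 0.1 d for purely
advective uptake and 0.01 d when $P > 0$, the regime where radial
exchange and soil depletion interact fastest; the analytic exchange
integrator is stable at larger steps but the defaults stay
conservative. Internal units are cm-day-gram throughout (permeabilities
quoted in m/s convert by ×8.64 × 10$^6$).

## What the shipped scenarios do and do not show

The scenario fixtures run at desk scale. `make_single_root_scenario()`
and `make_complex_rsa_scenario()` keep the published domain geometry
(0.9 × 0.9 × 145 cm$^3$ at 0.1 × 0.1 × 1 cm$^3$, and 75 × 15 × 145
cm$^3$ at 1 cm$^3$, laterally periodic), but their forcings are
synthetic: a sinusoidal transpiration season peaking at ≈5.5 mm/d of
column-equivalent transpiration, an early dry spell, one large rain
event around day 80 and a late dry period. They reproduce the
*structure* of a regulatory growing-season run — not any published
number, since those depend on external weather series and multi-year
warm-up states that are not bundled. The toy scenarios
(`make_toy_uniform_scenario()`, `make_top_heavy_scenario()`) are
deliberately minimal property-test beds (single-cell columns, ≤ 10$^4$
cells) on which exact statements hold:

* uniform concentration + advective-only uptake → daily TSCF = ε
  within 1 % once the root water has turned over (the root is a
  pass-through at steady state);
* uniform concentration + high permeability → cumulative collar mass
  within 5 % of the fully advective run (diffusion equilibrates the
  root to the soil, so export is transpiration × concentration either
  way);
* solute concentrated near the surface while water is taken up at
  depth, with P = 13.4 cm/d → daily TSCF well above 1: near-surface
  segments load diffusively, deep water dilutes the root solution and
  flushes it to the collar. The dilution mechanism requires spatially
  resolved concentrations; a 1D advective model cannot produce it.
* halving `dt_max` changes cumulative collar mass by < 2 % on the
  diffusive toy (self-convergence).

Test problem sizes were chosen so the whole suite exercises every
coupled path in a few minutes on one core: toy columns of 30-60 cells
over 2-12 days, the single-root column over 2-10 days, and a short
window of the complex scenario (the full-season complex run is a
multi-hour computation and is not part of the tests).

## Known limitations

* Neutral compounds only: no ionic speciation or ion trapping; no
  two-compartment (cortex/stele) root, no Michaelis-Menten active
  uptake, no salt exclusion.
* No hysteresis, macropores or water-table dynamics in the soil; no
  volatilisation or metabolite chains in the fate model; temperature is
  a prescribed forcing (a depth-damped annual sinusoid by default), not
  a solved field.
* The explicit sequential coupling (xylem → soil → solute) is
  first-order in time; the per-cell supply cap makes it robust but
  slightly anticipates water stress on coarse steps.
* Root growth does not respond to soil state, and third-order laterals
  are not generated (their absence is why the complex stand's root
  length density is low, about 0.1 cm cm$^{-3}$).

## A worked example

```{r, eval = FALSE}
sc <- make_toy_uniform_scenario(epsilon = 0.5, P = 0, days = 5)
run <- run_scenario(sc)
glance(run)   # cumulative transpiration, collar mass, closure error
tidy(run)     # daily T_act, m_upt, m_collar, C_mean, TSCF, PUF
autoplot(run) # daily TSCF/PUF
```

On this scenario the daily TSCF rises from 0.30 on day 0 (the root is
still filling) to 0.499 on day 4 — the advective fraction 0.5 to within
1 % — while the solute ledger closes to ~10$^{-16}$ relative.
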