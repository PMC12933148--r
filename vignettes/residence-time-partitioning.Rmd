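---
title: "Partitioning the biological pump by residence time: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning the biological pump by residence time: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqpump)
library(dplyr)
```

`seqpump` asks a simple question with awkward bookkeeping: of the organic
matter produced in the surface ocean, how much of its *regenerated*
inorganic product is still in the interior after a year, a century, a
millennium? This vignette documents the model equations, the synthetic
ocean used to exercise them, every numerical choice that required a
decision, and what the desk-scale results do and do not demonstrate.

## The steady-state cycle model

All tracers live on a set of wet boxes with volumes $v$ and a sparse
transport operator $A$ (s$^{-1}$), with the convention
$\dot c = A c + \text{sources}$. A physically admissible $A$ preserves
constants ($A\mathbf 1 = 0$) and conserves mass ($v^{\mathsf T}A = 0$);
`validate_operator()` reports both residuals and counts negative
off-diagonals, and `build_synthetic_transport()` refuses to return an
operator violating either invariant.

**Phosphorus.** Biological uptake is $\gamma\,[\mathrm{DIP}]$ on euphotic
boxes. The coefficient $\gamma$ is diagnosed once from the NPP climatology
and observed surface DIP, $\gamma = \mathrm{NPP} / (r_{C:P}(\mathrm{DIP}_{obs})\,
\mathrm{DIP}_{obs})$, so that the carbon value of modeled production matches
NPP when the model DIP matches the observations. Production splits into
particulate (POP), semilabile dissolved (DOP) and optionally labile
dissolved (DOP$_l$) phosphorus by fixed fractions
$(1-\sigma_{dop}-\sigma_{dopl},\ \sigma_{dop},\ \sigma_{dopl})$; fractions
are spatially uniform. POP export attenuates with depth following the
Martin power law $f(z) = f(z_0)(z/z_0)^{-b}$ below the euphotic base
$z_0$, with

$$ b = b_0 + b_\theta\,\bar\theta, $$

where $\bar\theta$ is the thickness-weighted mean temperature of the top
three model layers, normalized across water columns. Flux reaching the
seafloor remineralizes in the bottom wet box — there is no burial, so at
steady state the global production of each pool exactly balances its
remineralization (`steady_state_balance()` verifies this to $10^{-8}$
relative). Semilabile DOP decays with a Q10 law

$$ k = k_d\,Q_{10}^{(T-T_0)/10},\qquad T_0 = 30\,^\circ\mathrm C, $$

labile pools decay with a fixed 12-hour lifetime, and all decay returns to
DIP.

**Carbon.** Organic carbon production is the phosphorus production times a
phosphate-dependent stoichiometry

$$ r_{C:P} = (cc\,[\mathrm{DIP}] + dd)^{-1}, $$

so production is carbon-rich where phosphate is depleted ($1/dd$ is the
oligotrophic limit). The non-labile share splits into POC, semilabile DOC
and refractory DOC ($\kappa_r^{-1} = 16{,}000$ y, fixed); labile DOC
production is the residual $\max(0, \mathrm{NPP} - \text{non-labile
production})$, which lets total organic carbon production match the NPP
climatology while the interior tracers are controlled by the slower pools.
PIC is produced at a rain ratio times POC production and redissolves over
an e-folding depth. DIC and ALK are closed by fast surface restoring
toward reference values rather than by a carbonate-system gas-exchange
solver; the regenerated-tracer analysis — the package's target — only
involves sources that this closure does not touch. O$_2$ is carried with a
fixed 150:1 O$_2$:P stoichiometry and surface restoring to a linear-in-$T$
saturation; with a purely linear coupling it can go negative in poorly
ventilated deep boxes and should be read there as an oxygen deficit (the
linear analogue of suboxia). Non-negativity is guaranteed and checked for
the phosphorus and carbon tracers.

**Closure of the singular solve.** At steady state the coupled
P-system matrix is singular (total phosphorus is conserved), so one
redundant DIP equation — redundant because the volume-weighted block row
sums vanish — is replaced by the constraint that the volume-weighted
global-mean DIP equal the prescribed inventory (default
$2\times10^{-3}$ mol m$^{-3}$, a typical global mean). This is the
standard closure for matrix-transport models; the resulting equilibrium is
verified in the tests against an independently assembled dense system and
shown to be stationary under 2,000 years of forward integration.

## The synthetic ocean

`synthetic_grid()` + `build_synthetic_transport()` produce a closed
rectangular basin (default for the acceptance run: 12 latitude bands × 2
longitude cells × 8 geometrically thickening layers ≈ 4,000 m deep) with a
single-cell overturning streamfunction (default 20 Sv) discretized on cell
corners, upwind advection, and central diffusion
($K_h = 10^3$, $K_v = 10^{-4}$ m$^2$ s$^{-1}$ — canonical interior
values). A seeded lognormal jitter (sd 0.2) on the diffusive conductances
breaks the basin's symmetry without touching conservation. The euphotic
zone is the top two layers by default; real-ocean analyses vary in whether
they treat one, two or three surface layers as the production/restoring
region, so the count is a grid argument.

`make_forcing()` supplies what the full-scale analysis takes from
climatologies: an exponential-thermocline temperature field (28 °C
tropical surface, 2 °C abyss, 700 m scale, 14 °C equator-to-pole surface
contrast), a surface-DIP climatology richer at high latitudes, and an NPP
field shaped by surface DIP with a tropical envelope and seeded lognormal
heterogeneity, rescaled so its global integral is exactly the prescribed
total — 55 Pg C y$^{-1}$ by default, the satellite-era climatological
magnitude. Only the integral is constrained; the spatial shape is
configurable because the analysis constrains only the match to total NPP.

`make_observations()` turns an equilibrium into synthetic climatologies of
the six observed tracers (DIP, DOP, DIC, bulk DOC = sum of the three DOC
pools, ALK, O$_2$) with multiplicative lognormal noise (concentrations
stay positive) and an optional missing fraction. The "DOP" observation is
the semilabile pool: the labile pool's 12-hour lifetime leaves no
measurable standing stock. Ground truth is known by construction, which is
what makes parameter-recovery experiments meaningful.

What the synthetic ocean does **not** emulate: real geography and
topography, seasonality, spatially correlated observation errors, water-mass
structure beyond a single overturning cell, and the sheer dynamic range of
a 2°×2°×24-layer global grid. Passing tests therefore demonstrate
correctness of the machinery (conservation, first-passage accounting,
inversion identifiability at desk scale), not quantitative agreement with
full-scale results; the per-area productivity of the small basin is higher
than the real ocean's, so its production C:P and efficiencies are shifted
accordingly.

## Residence-time partitioning

For each organic pool $p$ the regenerated pulse is the pool's steady-state
remineralization field $r_p$ (mol m$^{-3}$ s$^{-1}$) — the residence clock
starts at remineralization, deliberately excluding the sinking interval,
so reported times underestimate full surface-to-surface transit by the
(short) sinking time. The pulse evolves by

$$ \dot R = A R - \Lambda R, $$

where $\Lambda$ restores the euphotic boxes to zero at 500 y$^{-1}$
(timescale 1/500 y), approximating an absorbing surface: raising the rate
tenfold changes year-and-longer fluxes by under 1% in the tests. The
surviving inventory $M_p(t) = v^{\mathsf T} R(t)$, converted with
12.011 g mol$^{-1}$ (C) or 30.974 g mol$^{-1}$ (P) and
$3.156\times10^7$ s y$^{-1}$, is the sequestration flux
$\Phi_{\tau\ge t}$ in Pg y$^{-1}$; at $t=0$ it equals the pool's global
production. Pool curves are computed independently and sum to the total by
linearity.

### Numerical choices

* **Scheme.** Trapezoid (Crank–Nicolson) steps with step-doubling: each
  step is taken once at $\Delta t$ and twice at $\Delta t/2$ and the
  Richardson-extrapolated combination kept; the difference is the local
  error estimate. The step lives on a geometric ladder
  $\Delta t = 10^{-3}\cdot1.2^{k}$ y capped at 10 y; the rung rises when
  the estimate is below a quarter of tolerance and falls when it exceeds
  it, so accepted step sizes repeat and the factorized propagators are
  reused. For systems up to 600 boxes the propagator
  $(I-\tfrac{\Delta t}2 B)^{-1}(I+\tfrac{\Delta t}2 B)$ is formed densely
  once per rung and each step is a single matrix–vector product; larger
  systems use cached sparse LU factorizations.
* **Tolerances.** Local tolerance $10^{-7}$ per step (the extrapolated
  value is typically two to three orders more accurate); on ≤500-box
  fixtures the integrator agrees with the dense matrix-exponential oracle
  $M(t) = v^{\mathsf T}\exp(t(A-\Lambda))\,r_0$ to better than $10^{-6}$
  at every output time. During the first $30/\text{rate}$ years — the
  stiff drain of the euphotic part of the pulse — the tolerance is relaxed
  to $10^{-4}$: resolving that transient fully would cost thousands of
  steps while only the euphotic fraction of the pulse (which is removed
  within days regardless) is affected.
* **Outputs.** The stepper lands exactly on every requested threshold, so
  reported values involve no output-time interpolation. The default
  threshold grid is $t=0$ plus log-spaced points; the output discretization
  is a free choice since the survival function is smooth in $\log t$.
  The integration horizon is whatever the threshold grid requests (2,000 y
  in the acceptance run); values beyond the computed span are refused, not
  extrapolated.
* **Monotonicity.** $M$ must not increase between steps beyond $10^{-9}$
  of $M(0)$; a violation aborts rather than silently smoothing.

## Inversion

The parameter misfit is
$f = \tfrac12\sum_x e_x^{\mathsf T} W_x e_x$ over the six observed
tracers, with $e_x$ = model − observation on observed boxes and $W_x$
diagonal with entries $v_i / (\sigma_x^2 V_{obs})$: volume-weighted so big
boxes count more, variance-normalized so tracers of different magnitudes
contribute commensurately (normalizing by the observation variance, rather
than a fixed prior error, is a choice and is exposed as an argument). No
explicit priors beyond bounds are applied — a flat prior in log-parameter
space. `fit_cycle_params()` runs L-BFGS-B with finite differences on
log-transformed parameters (all optimizable parameters are positive),
respects an evaluation budget, and treats a failed forward solve as a
$10^{12}$ penalty instead of an exception, so the search survives bad
corners of parameter space. The full-scale analysis this mirrors uses
adjoint gradients and 21 optimized parameters; here the contract is the
objective, not the search algorithm, and the registry of optimizable
parameters (`param_bounds()`) is data-driven so the set can be edited
without code changes. On the 200-box synthetic ocean, the four phosphorus
parameters $(b_{P0}, b_{P\theta}, k_{dP}, Q_{10P})$ are recovered within
15% from 5%-noise observations inside 500 objective evaluations — the
identifiability check the acceptance suite runs.

## Experiments

* `run_labile_dop_sensitivity()` routes a share (1–60%) of total
  organic-P production into an added labile DOP pool with the same 12-hour
  lifetime as labile DOC, reducing the POP residual; the carbon cycle is
  held fixed by caching the base run's curves, so only phosphorus curves
  and the C:P ratio recompute. More labile routing raises total P
  production (faster recycling), drains the ≥1-year P flux, lowers the
  short-horizon C:P and raises the century-horizon C:P.
* `run_equal_remin_experiment()` removes the elemental asymmetry either by
  copying carbon's remineralization parameters onto phosphorus
  (`P_from_C`) or by giving both elements uniform values (`means`,
  defaults $b = 1.28$, $k = 0.057$ y$^{-1}$ — the full-scale flux-weighted
  reference values). It is a pure override: nothing is re-optimized
  afterwards. Efficiency differences are reported as
  $(\text{base}-\text{alt})/\text{alt}$, the "percent lower" convention;
  the sign is negative when the base model sequesters less efficiently.
* `run_perturbation_accounting()` converts efficiencies into the retained
  mass of a marginal production increase (e.g. 1 Pg C of fertilization-induced
  production), which is linear by construction.

Every pipeline is a pure function of (configuration, seed): all randomness
(conductance jitter, NPP heterogeneity, observation noise, start jitter)
flows through explicit seeds via a private RNG stream that leaves the
session's RNG untouched.

## Problem sizes and interfaces

The test suite runs on fixtures from 2 to 200 boxes; the acceptance script
uses a 192-box ocean with a 2,000-year horizon and finishes in a few
minutes on one core — sizes chosen so the dense first-passage oracle stays
usable as a cross-check. Transport archives are plain text (a JSON header,
a CSV box table, and coordinate-triplet CSV for the operator) with units
recorded and auto-detected (s$^{-1}$ vs y$^{-1}$) on read; parameters read
and write a `key: value` text format; curves export to CSV with one column
per pool.

## Known limitations

No seasonal or transient dynamics (steady circulation only); no burial,
nitrogen cycle, iron limitation, or carbonate-system chemistry; particulate
standing stocks are diagnostic only (flux over a nominal 100 m d$^{-1}$
sinking speed) because the particle flux is treated as an instantaneous
Martin-curve redistribution; posterior uncertainty of fitted parameters is
not quantified (point estimation only); and the desk-scale ocean's
numbers, while internally consistent and fully reproducible, are not
calibrated to the real ocean's.
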