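---
title: "Collective growth of microtubule asters: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective growth of microtubule asters: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asterwave)
```

## The model

Interphase asters in large embryonic cells span hundreds of micrometres while
individual microtubules are dynamically unstable and, on average, shrinking.
`asterwave` implements a model in which aster growth is a *collective*
phenomenon: existing microtubules stimulate the nucleation of new ones, and
the aster front advances because microtubules are born faster than they die,
each daughter displaced outward toward its mother's plus end.

A single microtubule is a two-state particle: its plus end polymerizes at
`vg` (um/min) until a catastrophe (rate `fcat`, 1/min) switches it to
depolymerization at `vs`, from which a rescue (rate `fres`) switches it back.
The time-weighted net drift

$$J = \frac{v_g f_{res} - v_s f_{cat}}{f_{res} + f_{cat}}$$

separates the *bounded* regime (J < 0: every microtubule eventually shrinks
back to zero length and disappears) from the *unbounded* one. In the bounded
regime the steady-state length distribution is exponential with mean
$\langle l \rangle = v_g v_s / (v_s f_{cat} - v_g f_{res})$.

New microtubules nucleate at zero length at existing growing plus ends (rate
`r` per plus end) or along the polymer lattice (rate `p` per um), saturating
logistically at a carrying capacity `K` of the local growing plus-end density
$C_g$: plus-end mode uses $Q = r\,C_g(1 - C_g/K)$. Mean-field dynamics of the
densities $\rho_g(t, x, l)$, $\rho_s(t, x, l)$ of growing/shrinking
microtubules with minus end at $x$ and length $l$ are a pair of
length-structured transport equations coupled only through the nucleation
term.

The analytic results implemented in `R/analytic.R` are:

* a critical plus-end nucleation rate $r_c = f_{cat} - (v_g/v_s) f_{res}$,
  the reciprocal of the mean time a microtubule spends growing — growth
  requires each microtubule to nucleate at least one daughter per lifetime;
* a closed-form front velocity $V(r)$ valid on $r_c < r < f_{cat}$
  (`aster_velocity()`);
* a *gap velocity* $V_{gap} = -v_g v_s (v_g f_{res} - v_s f_{cat}) /
  (v_g^2 f_{res} + v_s^2 f_{cat})$, the limit of $V$ as $r \to r_c^+$: the
  onset of growth is explosive, with no steady speeds between 0 and
  $V_{gap}$;
* the analogous polymer-mode threshold $p_c$, the reciprocal of the expected
  time-integrated length $E[\int l\,dt] = v_g v_s (v_g + v_s) /
  (v_s f_{cat} - v_g f_{res})^2$ of one lifetime (a first-passage quantity
  derived from the backward equations and validated here by brute-force
  simulation);
* the bulk density fixed point $C_g^{bulk} = K(1 - r_c/r)$, where logistic
  suppression tunes the effective nucleation rate to exactly one daughter per
  microtubule.

```{r analytics}
p <- dynamics_params(vg = 30, vs = 42, fcat = 3.3, fres = 2.0)
analytic_summary(p, nucleation_spec("plus_end", rate = 2.1,
                                    carrying_capacity = 0.4))
```

## Parameter inference

`fres` and `r` are not directly observable in extract experiments, but `V`
(rate of radius increase) and `V_gap` (slowest observed growth speed at the
arrest transition, e.g. under a depolymerase titration) are.
`infer_rescue_from_gap()` inverts the gap-velocity formula in closed form
(it is linear in `fres`); `infer_nucleation_from_velocity()` then bisects the
velocity formula on $(r_c, f_{cat})$, where $V$ is strictly increasing —
bisection rather than a derivative-based method because of the square-root
singularity at $r_c$. Measured velocities below $V_{gap}$ are refused: the
model admits no asters growing slower than the gap velocity, which is also
why the inversion is well posed.

```{r inference}
fit <- infer_aster_dynamics(tibble::tibble(
  vg = 30, vs = 42, fcat = 3.3, v = 22.3, v_gap = 12.8, cg_bulk = 0.053))
tidy(fit)
```

The carrying-capacity inversion `K = cg_bulk * r / (r - rc)` is flagged
approximate: the logistic fixed point describes the bulk only to tens of
percent, so `K` is an order-of-magnitude estimate. Measurement uncertainties
are not propagated; the published error bars serve as comparison tolerances
only.

## The deterministic solver

`simulate_aster()` integrates the transport equations on a shared
$(x, l)$ grid (`dx = dl`, so plus-end positions land on nodes) in 1-D planar
geometry with all microtubules oriented plus-end outward. Design choices that
matter:

* **Exact advection.** The time step is commensurate: `vg*dt/dx` and
  `vs*dt/dx` are the smallest integers approximating `vg : vs` within 1%, so
  polymerization and depolymerization are exact column shifts with no
  numerical diffusion. Shrinking mass crossing $l = 0$ is removed
  (non-centrosomal microtubules disappear); with
  `centrosome_renucleation = TRUE`, mass dying in the $x = 0$ cell re-enters
  the growing state at zero length.
* **Exact switching kernel, Strang-split.** Catastrophe/rescue exchange uses
  the matrix exponential of the two-state generator over half a step on
  either side of the advection. A forward-Euler exchange at the commensurate
  `dt` is qualitatively wrong here: the net growth rate of the population is
  a small difference of the large opposing exchange fluxes, and the
  first-order Euler error can flip its sign (we measured -0.054/min instead
  of +0.167/min at `dx = 0.5` for the reference supercritical set).
* **Compounded nucleation deposit.** Newborn mass over a step is
  $C_g(e^{q\,dt/C_g} - 1)$ rather than $q\,dt$ (exact for the rescue-free
  subsystem, where daughters of daughters contribute at the same rate), and
  is spread over the first `vg*dt/dx` length cells — the growth a newborn
  accumulates between a uniform-in-time birth and the end of the step.
  Polymer mode uses the plain first-order deposit (its per-plus-end rate is
  unbounded, so compounding does not apply).
* **Stability/accuracy guard.** `max(fcat, fres) * dt < 0.1` is enforced by
  halving `dx` (the commensurate `dt` scales with `dx`); for the reference
  rates the default request of 0.5 um refines to 0.25 um.
* The inner loop is compiled; the exported `step_state()` is the pure-R
  reference implementation, and the test suite asserts the two agree to
  machine precision.

Two physical points discovered while validating the solver are worth
recording. First, behind a pulled front the wake drains: every daughter is
displaced toward its mother's plus end, so without a centrosomal source the
interior of the aster slowly empties outward and only a band behind the front
sits at the bulk fixed point. Reference-style simulations therefore switch
centrosomal re-nucleation on; the front speed is insensitive to this choice
(the front dynamics are autonomous of the seed), and the wake heals toward
$K(1 - r_c/r)$ over a length of order (outward drift)/(local regrowth rate),
roughly 150 um for the reference set. Second, front tracking uses a *single
fixed threshold* for the whole trace — half the final-profile plateau,
excluding the origin cell where re-nucleated mass piles up, with 1% of `K` as
the fallback when no plateau forms. A time-varying half-max threshold
systematically inflates the fitted speed while the wake is still filling in.
The fitted speed converges to the analytic value from below like $1/t$ (the
usual slow relaxation of pulled fronts), so speed measurements use runs of
20-30 min of simulated time and fit the last half of the trajectory; at
`dx = 0.25` the reference supercritical set gives 27.5 vs 27.585 um/min
analytic.

Problem sizes: the front-speed checks use `dx = 0.25` um on domains of
500-900 um for 20-30 min of simulated time (a few seconds each with the
compiled kernel); regime classification (stationary vs traveling) uses
100 um domains.

## The stochastic oracle

`simulate_lifetimes()` draws exact exponential waiting times between state
switches — trajectories are piecewise linear, so per-segment statistics
(time growing, $\int l\,dt$, maximal plus-end excursion) accumulate without
discretization error. It is the package's brute-force check on the two
critical-rate formulas: mean time growing $= 1/r_c$ and mean integrated
length $= 1/p_c$.

`simulate_branching()` grows whole populations (saturation off, $K = \infty$)
with daughters born growing, at zero length, at the mother's current plus-end
position; mother and daughter live and die independently. Plus-end-mode
nucleation is a Poisson process over growing segments; polymer-mode rates
$p\,l(t)$ are time-inhomogeneous and sampled exactly by inverting the
per-segment quadratic cumulative hazard. Extinction of this branching process
brackets the critical nucleation rate, and the survival probability is
cross-checked in the tests against the offspring generating-function fixed
point $q = E[e^{-r(1-q)T_g}]$ computed from the lifetime sampler — two
independent routes to the same number. At the reference supercritical rate
(`r = 2.5`, 11% above critical) the survival probability is only about 7.5%:
near-critical branching processes die young, which is why stationary-looking
asters just below threshold and exploding ones just above can look similar
for a while.

The mean-field front speed bounds the stochastic front from above at modest
population sizes; the test asserts the rightmost-plus-end slope of surviving
populations lies in $[0.7, 1.1] \times V$ — deliberately loose, since the
magnitude of the finite-population correction is not part of the model's
claims.

## Measurement emulation

The imaging pipeline is implemented against synthetic data so it is testable
without microscopy:

* `synth_comet_lifetimes()` draws exponential plus-end comet lifetimes at
  rate `fcat` and quantizes them upward to the 2 s frame interval.
  `fit_catastrophe_rate()` bins them at the frame interval and fits a line to
  log-counts inside a 5-60 s window (early tracking artefacts and the
  censored tail excluded), with a bootstrap standard error; the
  discretization-aware MLE
  $\hat\lambda = \log(\bar d / (\bar d - \Delta)) / \Delta$ is offered as an
  alternative and agrees within standard errors on clean data. Memorylessness
  makes the fit window-invariant, which the tests exploit.
* `synth_aster_profiles()` emulates 1-D intensity profiles: a sigmoidal edge
  on a plateau translating at constant speed, sampled every 2 min with
  additive noise. `extract_radius()` applies a centered moving average (the
  low-pass filter's exact form is unspecified in the source procedure, so the
  window width is a configurable default of 9 samples) and takes the
  outermost half-max crossing; a profile whose smoothed peak is within 4
  noise standard deviations of background is scored "no edge".
  `velocity_from_radii()` fits the radius series by least squares and scores
  slopes below 0.5 um/min as `V = 0`, mirroring how stationary or shrinking
  asters are scored.

What the generators deliberately do not emulate: photobleaching, uneven
illumination, tracking errors that truncate comet tracks non-exponentially,
and radial-geometry intensity falloff. Passing the recovery tests therefore
demonstrates the estimators are correct on their stated model, not that they
are robust to every imaging artefact.

## Degenerate inputs and numerical conventions

All rates are per minute, speeds in um/min, lengths in um; no unit conversion
happens inside the model functions. `J >= 0` makes the bounded-regime
quantities diverge: `mean_mt_length()` and `expected_integrated_length()`
return `Inf` with a warning, `polymer_critical_rate()` returns 0 (no
threshold), `gap_velocity()` returns `NA`. `aster_velocity()` never
extrapolates outside $(r_c, f_{cat})$ — it returns `NA` with a flagging
warning and callers fall back on the simulator; the single boundary point
$r = f_{cat}$ at $f_{res} = 0$ is kept by continuity ($V = v_g$ exactly),
one of the two limit identities that pin the formula's algebra (the other is
$V(r \to r_c^+) = V_{gap}$, approached like $\sqrt{r - r_c}$). At `fres = 0`
the critical rate equals `fcat` exactly and the validity window is empty.

The polymer-mode logistic factor uses the local growing plus-end density
(not the polymer density) — the saturation variable is not pinned down by the
model's source, and this choice keeps the two modes' bulk fixed points
directly comparable.

## Limitations

1-D planar geometry only; no radial dilution, bundling, motor transport or
mechanics. Mean-field front speeds carry no finite-population (stochastic
front) corrections. The bulk-density fixed point describes the measured bulk
plus-end density only to tens of percent, so carrying-capacity inversion is
approximate by construction.
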