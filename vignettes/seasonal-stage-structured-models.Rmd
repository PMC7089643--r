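---
title: "Seasonal consumer-resource dynamics: cohort model and stage-structured approximation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal consumer-resource dynamics: cohort model and stage-structured approximation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seastage)
```

## The modelling problem

Many temperate species reproduce once a year but grow, feed and die
continuously in between. A population of such a species cannot be described
by discrete-time equations (individuals change between reproductive events)
nor by a plain continuous-time model (reproduction is a pulse, not a rate).
`seastage` implements the resulting *semi-discrete* consumer-resource system
in two interchangeable forms:

* a **cohort-based physiologically structured population model (PSPM)**, in
  which every annual cohort is tracked as a triple (number density $c_i$,
  body size $s_i$, per-capita reproductive storage $g_i$), and
* a **stage-structured biomass model**, a fixed set of ODEs for juvenile
  biomass (optionally split over $n$ sub-stages $J_1 \dots J_n$), adult
  biomass $A$, a reproductive-storage pool $B$ and the resource $R$.

The second is an approximation of the first, built so that the two share
identical individual-level energetics; the package exists to simulate both
and to quantify when the cheap approximation can stand in for the expensive
cohort model.

## Individual-level energetics

All rates are mass-specific. Ingestion follows a Holling type II functional
response $R/(H+R)$; intake is assimilated with efficiency $\sigma$ and first
pays maintenance $T$. Net biomass production is

$$\nu_J(R) = \sigma (2-q) M \frac{R}{H+R} - T, \qquad
  \nu_A(R) = \sigma q M \frac{R}{H+R} - T,$$

where $q \in (0,2)$ tilts foraging performance between juveniles ($q<1$:
juveniles superior) and adults ($q>1$). Negative $\nu$ means starvation: the
shortfall is paid as extra mortality, $d(R) = \mu - \min(\nu, 0)$, while
growth, maturation and reproductive investment use only the positive part
$\nu^+$. Juveniles spend $\nu^+_J$ on somatic growth from birth size $S_b$
to maturation size $S_m$; adults do not grow and route $\nu^+_A S_m$ per
capita into storage $g$, the capital that funds the next reproduction
pulse. Stored biomass is inert: it does not forage, pays no maintenance,
and dies with its owner. The resource renews by semi-chemostat growth
$\delta(R_{max} - R)$.

Across species, $M$, $T$ and $\mu$ scale with the characteristic adult mass
$W_A$ as $0.1\,W_A^{-1/4}$, $0.01\,W_A^{-1/4}$ and $0.0015\,W_A^{-1/4}$
day$^{-1}$ — the classic fast-slow spectrum: a 0.02 g species lives about
250 days and sees one reproductive opportunity, a 200 g species about 2500
days and ten.

## Parameters

| symbol | unit | meaning | default |
|---|---|---|---|
| $M$ | day$^{-1}$ | mass-specific maximum ingestion | $0.1\,W_A^{-0.25}$ |
| $T$ | day$^{-1}$ | mass-specific maintenance | $0.01\,W_A^{-0.25}$ |
| $\mu$ | day$^{-1}$ | background mortality | $0.0015\,W_A^{-0.25}$ |
| $W_A$ | g | characteristic adult body size | 50 |
| $H$ | mg L$^{-1}$ | half-saturation resource density | 3 |
| $q$ | — | stage competition asymmetry | 1 (0.5 / 1.5 in asymmetric scenarios) |
| $\sigma$ | — | assimilation efficiency | 0.5 |
| $z$ | — | birth/maturation size ratio | 0.1 |
| $Y$ | days | season length between pulses | 250 |
| $S_m$, $S_b$ | g | maturation and birth size | $W_A$, $z S_m$ |
| $R_{max}$ | mg L$^{-1}$ | resource maximum | 20 |
| $\delta$ | day$^{-1}$ | resource turnover | 0.1 |

Individual sizes are in grams; all population-level quantities ($J$, $A$,
$B$, $R$, $c_i s_i$) share the resource's density unit (mg L$^{-1}$), so
number densities $c_i$ carry mg L$^{-1}$ g$^{-1}$ and consumer ingestion
couples to the resource without a conversion constant.

## The two population models

**PSPM.** Within a season, each juvenile cohort obeys
$\dot c_i = -d_J c_i$, $\dot s_i = \nu^+_J s_i$, $\dot g_i = 0$; each adult
cohort ($s_i = S_m$) obeys $\dot c_i = -d_A c_i$, $\dot s_i = 0$,
$\dot g_i = \nu^+_A S_m$. When the largest juvenile cohort reaches $S_m$ it
is relabelled adult — numbers, size and storage unchanged — which is a
discrete event located by root-finding. At each season boundary $t_n = nY$
all storage converts at once into a newborn cohort:
$c_0 = \sum_i g_i c_i / S_b$ at size $S_b$, all $g_i$ reset to zero, $R$
untouched. Both maps conserve total consumer biomass exactly.

**Stage model.** Summing cohort biomass per stage and replacing the
size-triggered maturation event with a size-independent per-capita rate
$\gamma$ gives, for one juvenile stage,

$$\dot J = \nu^+_J J - \gamma J - d_J J,\quad
  \dot A = \gamma J - d_A A,\quad
  \dot B = \nu^+_A A - d_A B,$$

with the pulse map $J \mathrel{+}= B$, $B = 0$. The maturation rate is
derived, not fitted: demanding that at any fixed resource density the
expected lifetime biomass a newborn delivers to the adult stage equals the
cohort model's value $S_m z^{\mu/\nu_J}$ forces

$$\gamma(\nu_J, d_J) = \frac{\nu_J - d_J}{1 - z^{\,1 - d_J/\nu_J}}
  \quad (\nu_J > 0), \qquad \gamma = 0 \text{ otherwise.}$$

The expression has a removable singularity at $\nu_J = d_J$ with limit
$-d_J/\ln z$. We evaluate it as
$\gamma = \nu_J\, w / (-\ln z \cdot \mathrm{expm1}(w))$ with
$w = (1 - d_J/\nu_J) \ln z$, which is branch-free, exactly continuous
through the limit and accurate uniformly in $|\nu_J - d_J|$ — we preferred
this reformulation over a local series expansion because it removes the
switching threshold entirely.

**Multiple juvenile stages.** With $n$ juvenile stages the size range is
split evenly on a log scale (per-stage entry/exit ratio $z^{1/n}$), all
stages share $\nu_J$, $d_J$ and the $(2-q)$ foraging weight, and biomass
flows along the chain at the common rate
$\gamma_n = \gamma(\nu_J, d_J, z^{1/n})$. Under constant conditions the
time at which biomass matures is then gamma-distributed (exponential for
$n=1$), while each stage multiplies the expected throughput by
$z^{(\mu/\nu - 1)/n}$, so the chain preserves the overall expected
contribution $S_m z^{\mu/\nu}$ for every $n$. The identical stage rates are
forced by this construction: unequal rates would break the equal-throughput
split while the stages are, by assumption, energetically indistinguishable.
In the cohort model the same curve is a step function (all members of a
cohort mature at once at age $-\ln(z)/\nu_J$); `cumulative_maturation_curve()`
computes both. Three stages already concentrate maturation enough to
recover most of the cohort model's cycling behaviour.

## The season engine and its numerical choices

* **Seasons are contiguous.** Winter is not simulated — the biological
  assumption is that all rates become negligible then — so season $n$ spans
  $[nY, (n+1)Y)$ and the pulse closes it. Year boundaries are hit exactly
  because each season is integrated as its own segment of length $Y$.
* **Integration.** `deSolve::lsodar` (PSPM, with the maturation root
  function) and `deSolve::lsoda` (stage model), rtol $10^{-8}$, atol
  $10^{-10}$. Dense output on a fixed 1-day grid by default; pre- and
  post-pulse rows are recorded separately so discontinuities are never
  interpolated across. Setting `sample_interval = NA` records only season
  boundaries, which long attractor runs use.
* **Events.** Maturation roots are located by the solver and the matured
  cohort's size is pinned to exactly $S_m$; adult stage membership is an
  explicit flag, so a cohort caught exactly at $S_m$ by the root finder
  cannot be misclassified, and adult sizes cannot drift. If a maturation
  root coincides with a year boundary the maturation is applied first
  (the maturing cohort has $g = 0$, so the order cannot move biomass).
* **Culling.** Cohort number densities decay exponentially forever; cohorts
  whose biomass falls below $10^{-12}$ of the total are removed after each
  pulse, keeping the cohort count near the ~100–140 a long run actually
  needs. The removed biomass is logged and stays far below $10^{-9}$ of the
  total.
* **Initial conditions** (the source models leave them open): resource at
  $R_{max}$, one newborn inoculum of 0.1 mg L$^{-1}$ at $t = 0^+$ —
  biologically, an invasion attempt by a small founding cohort just after a
  nominal reproduction instant. Configurable via `sim_config(init = )`.
* **Determinism.** There is no randomness anywhere; identical
  configurations produce bit-identical traces.

## The experiment protocol

`bifurcation_sweep()` steps a parameter ($q$, $W_A$ or the stage count)
along a grid, warm-starting each run from the previous final state (when
$W_A$ changes, cohort sizes are mapped into the new $[S_b, S_m]$ range).
Summaries per step: trapezoidal time averages over the trailing 60 % of the
step, post-reproduction biomasses over the trailing 5 % window, the cycle
amplitude (max − min of post-pulse totals) and reproduction-gap statistics.
A season counts as "without reproduction" when its newborn pulse is below
$10^{-6}$ of total consumer biomass — the sources give no cutoff; skipped
pulses are structurally zero in the PSPM and many orders of magnitude below
normal pulses in the stage model, so the statistic is insensitive to this
choice over a wide range. Grids run ascending by default (no direction is
prescribed); descending grids are available for hysteresis checks, and on
fixed-point regimes the two directions agree to $10^{-4}$.

The full-scale protocol uses 200,000-day steps; the package defaults to
20,000-day steps, which resolve the same attractors at desk scale. The test
suite uses 100-season runs for the cross-model comparisons at $W_A = 50$
(where rates are slow and transients long but cycles simple) and 800-season
runs at $W_A = 1$ for the reproduction-gap statistics (where rates are ~2.7×
faster and the attractor is reached well before mid-run); the acceptance
script uses the 800-season protocol with the first half discarded.

## What the scenarios do and do not emulate

The presets (`symmetric`, `adult_superior`, `juvenile_superior`,
`small_juvenile_superior`) are parameter points, not data: they emulate the
qualitative regimes of seasonal consumer-resource dynamics — convergent
seasonal oscillations at $q = 1$, adult-driven slow cycles at $q = 1.5$,
juvenile-driven single-cohort cycles at $q = 0.5$ and small $W_A$ — under
idealized assumptions: deterministic identical individuals within a cohort,
a single unstructured resource, externally fixed and perfectly synchronous
spawning, no winter mortality, irreversible storage. Passing tests
therefore demonstrate internal consistency of the two model translations
and their numerical treatment, not fidelity to any field system; in real
populations, individual variation is known to blur the sharp single-cohort
cycles the deterministic PSPM produces.

## Degenerate inputs and edge behaviour

Empty consumer states reduce both models to the analytic semi-chemostat
recovery $R(t) = R_{max} - (R_{max} - R_0)e^{-\delta t}$, which the tests
compare against solver output. Zero storage at a boundary produces no
newborn cohort (PSPM) or an identity pulse (stage model). Starvation
($\nu < 0$) stops growth, maturation and investment simultaneously and
augments mortality by exactly $-\nu$; total biomass then satisfies the same
production-minus-mortality balance the tests check along trajectories.
Non-positive $\nu_J$ yields $\gamma = 0$ and a flat maturation curve.

## Known limitations

* One consumer species, one resource; no temperature or photoperiod
  forcing; season length is fixed, not stochastic.
* Stored energy is irreversible — it cannot be burned to survive winter or
  starvation, so severe starvation late in a season wastes the storage of
  adults that die before the pulse.
* The stage model underestimates cycle amplitude when juveniles are
  competitively superior (juvenile-driven single-cohort cycles); its
  averages then deviate from the cohort model — this is a property of the
  approximation, reproduced (not fixed) by the package, and is quantified
  by `compare_models()`.
* The explicit-solver default can reject many steps if parameters are
  pushed far outside the documented ranges; tolerances are configurable
  through `sim_config()`.
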