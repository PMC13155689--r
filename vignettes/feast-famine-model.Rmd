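---
title: "Modeling generalist–specialist dynamics under feast–famine cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling generalist–specialist dynamics under feast–famine cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feastfamine)
```

## The model and its assumptions

`feastfamine` simulates N microbial phenotypes competing for nutrients that
arrive as discrete pulses. A pulse at time $\tau_k$ sets the nutrient
amount to $S_0$ and selects one of $E$ nutrient types; that type defines
the current environment $e$ until the next pulse. While $S > 0$ (feast),
phenotype $i$ grows exponentially at $\mu_{i,e}$ and consumes nutrient
with unit yield; when $S = 0$ (famine) it dies at $\gamma_{i,e}$. A
dividing cell of phenotype $j$ places its daughter in a neighboring
phenotype $i$ with probability $A_{ji} = p$, so switching acts only during
feast and the total growth flux is conserved: the inflow term is
$A_{ji}\mu_{j,e}X_j$, which keeps $\sum_i \dot X_i = \sum_i \mu_{i,e}X_i$
equal to the consumption rate $-\dot S$. (A non-conserving variant with
inflow coefficient $A_{ij}A_{ji}$ is available behind
`sim_config(literal_switching = TRUE)` for sensitivity checks; it is not
the model.)

Assumptions worth keeping in mind:

- growth is nutrient-concentration independent during feast (no Monod
  kinetics) and death is strictly exponential during famine;
- at most one nutrient type is present at a time: a pulse overwrites both
  the environment and any leftover nutrient ($S := S_0$, leftovers
  discarded);
- population discreteness enters only through the extinction threshold
  $\theta$, applied at supply events and nowhere else; a zeroed phenotype
  can be re-seeded by switching;
- demographic (birth–death) noise and spatial structure are absent — the
  only randomness is the supply process.

Two constraints define the strategy space. The *resource-use trade-off*
fixes the geometric mean of each phenotype's growth rates across
environments, $(\prod_e \mu_{i,e})^{1/E} = \bar\mu$ — a strong (convex)
trade-off, so improving growth on one nutrient costs more than
proportionally on the others. The *growth–death trade-off*
$\gamma = a\,e^{b\mu}$ makes fast growers fast diers under starvation, in
line with starvation-survival measurements in *E. coli*.

## Parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| $\bar\mu$ | geometric-mean growth rate (trade-off level) | 1/time | scan variable |
| $a$ | death rate of a non-grower | 1/time | 0.01 |
| $b$ | growth–death trade-off strength | time | 1 |
| $S_0$ | nutrient amount per pulse | population units | 10 |
| $p$ | per-division switching probability | — | 1e-4 |
| $\theta$ | extinction threshold at pulses | population units | 1e-8 |
| $\Delta\tau$ | inter-pulse interval | time | Γ(shape 2, scale 50) or constant 100 |

The reference interval distribution is gamma with shape 2 and scale 50
(mean 100, variance 5000). The distribution's second parameter is read as
a *scale*: a rate-50 reading would give mean 0.04, three orders of
magnitude below the paired constant-interval setting of 100 used
throughout the scans, so the scale reading is the only consistent one.
`make_spec_mean_variance()` moment-matches gamma, uniform and normal
families to a requested mean and variance; the normal family is rejection
sampled on $(0,\infty)$ rather than clipped, keeping the conditional
density smooth.

## Numerical design

During feast the dynamics are linear, $\dot X = M X$ with
$M = K\,D_\mu$, $K$ symmetric whenever the switching adjacency is
symmetric. $M$ is then similar to the symmetric matrix
$D_\mu^{1/2} K D_\mu^{1/2}$, so its eigendecomposition is real and
numerically stable; it is computed once per environment per run. With unit
yield, $S(t) = S_0 - (\sum_i X_i(t) - \sum_i X_i(0))$, so the depletion
time $T^+$ solves a scalar monotone equation in the spectral coordinates.
It is bracketed by bisection (overflowing evaluations count as "past
depletion"; all spectral terms are evaluated in log scale so tiny
coefficients never meet `Inf`) and polished with Newton steps, giving
per-cycle mass balance $\sum_i \Delta X_i = S_0$ at ~1e-10 relative and
making the integrator exact rather than time-stepped. Famine is the closed
form $X_i e^{-\gamma_i t}$. Time averages integrate these closed forms
segment by segment, clipped analytically at the window edges — no
quadrature error. The test suite cross-checks whole trajectories against a
generic stiff ODE integration with event detection (`deSolve::lsodar`) at
1e-6 relative.

Degenerate inputs: a fully extinct population simply fails to deplete
(feast spans the interval, $S$ leftover until the next pulse overwrites
it); `p = 0` makes $M$ diagonal and phenotypes exactly independent;
a pulse landing exactly at `t_end` is dropped (its cycle has zero length).
The initial state is $X_i = 1$ for all phenotypes with famine on
$[0, \tau_1)$; which environment's death rates apply before the first
pulse is undefined in the model, so environment 1 is used (configurable
via `sim_config(env0 = )`) — it affects a single transient segment far
outside every averaging window.

## Theory: invasion analysis and branching

Coarse-graining the environments ($\langle\mu\rangle, \langle\gamma\rangle$
= arithmetic means of the rates — not $\gamma$ evaluated at the mean
$\mu$) gives the per-cycle net log growth
$f_i = \mu_i T^+ - \gamma_i(\Delta\tau - T^+)$. A monomorphic resident at
steady state has $f_\alpha = 0$, fixing
$T^+ = \Delta\tau\,(1/\mu_\alpha)/(1/\gamma_\alpha + 1/\mu_\alpha)$, and a
rare invader's fitness factorizes so that its sign equals the sign of
$\mu_\beta/\gamma_\beta - \mu_\alpha/\gamma_\alpha$: the phenotype with
the larger growth-to-death ratio $r$ wins, and the generalist/specialist
transition sits exactly at $r_g/r_s = 1$.

For a continuum of strategies $\mu_{A,B} = \bar\mu e^{\pm t}$ the relevant
question is whether the symmetric point $t = 0$ extremizes $\log r(t)$.
Its curvature is computed by Romberg-extrapolated symmetric differences
(the function is even in $t$; five step halvings from $h_0 = 0.4$ reach
~1e-10, verified against the closed form below). For the exponential
trade-off the curvature is $1 - u - u^2$ with $u = b\bar\mu$: *positive*
below the branching point $\bar\mu^* = (\sqrt5 - 1)/(2b)$ — the symmetric
strategy is a local minimum of $r$, specialization pays, and the abundance
distribution on the ladder turns bimodal — and negative above, where the
generalist peak is stable. `branching_mu_bar()` returns the numeric root;
the closed form is kept as an independent cross-check, matching to 1e-8
across $b \in \{0.5, 1, 2, 4\}$.

For sparse supply, the specialists' temporal average under constant
intervals follows $X_s \sim e^{d\Delta\tau}/\Delta\tau$ over the
intermediate range where famines level the field before each pulse. The
constant $d$ is deliberately treated as a *fit* parameter
(`fit_specialist_scaling()`, ordinary least squares after moving the known
$-\log\Delta\tau$ term to the left); the tested contract is the functional
form, not a derived value of $d$. Time-averaging over a random interval
distribution turns this into a cumulant series,
$\langle X_s\rangle \sim \exp(\sum_n d^n\kappa_n/n!)/E[\Delta\tau]$,
truncated at order 4 by default with a warning when the next term exceeds
1e-3 of the retained sum — all coefficients are positive, so variance in
the supply interval always helps the specialists in this regime.

## What the scans emulate — and what they do not

The synthetic supply schedules reproduce the study conditions: renewal
processes (constant, gamma, uniform, truncated-normal intervals) with
independent interval and nutrient-type streams derived deterministically
from one base seed, and either uniform-random or deterministic cycling
nutrient choice. They do *not* emulate correlated (non-renewal) supply,
nutrient-type-dependent pulse sizes, or any feedback from the community
onto the supply — passing tests say nothing about such settings, nor about
demographic stochasticity at low abundance, where the threshold $\theta$
is only a crude stand-in for discreteness.

Scan problem sizes are the package's defaults, chosen so that each scan
sits far past its transient while remaining quick: three-phenotype scans
run to $t = 6\times10^4$ (several hundred cycles) with the averaging
window $[5\times10^4, 6\times10^4]$ and 5 replicates; the steady
time-averaged state is reached within a few hundred cycles, and doubling
the horizon moves the reported averages well within their standard errors.
Ladder ($N = 51$, $\Delta\tau = 10$, alternating environments) and simplex
($E = 3$, cycling) scans run to $t = 2\times10^4$ and average the last 20
and 30 supply intervals respectively. Full-scale settings are plain
arguments (`t_end`, `window`, `n_replicates`).

Design choices that were genuinely open:

- the ladder normalization $g(0) = m^{-c(N+1)/2}$ is read so the central
  rung is exactly the generalist ($\mu_A = \mu_B = \bar\mu$), the only
  reading producing a symmetric strategy axis; it is asserted at
  construction;
- adjacency is stored as an explicit symmetric relation rather than
  $|i-j|=1$ arithmetic, so the chain and the E = 3 simplex lattice share
  one switching-matrix code path;
- for $E > 2$ the ratio $r$ averages over all environments, the natural
  extension of the two-environment definition;
- the simplex lattice radius (`extent`, default 5) is a free parameter —
  the qualitative center-versus-edges result is insensitive to it;
- per-column normalization of ladder heat-maps is per phenotype (no
  binning), with zero abundances floored at the smallest positive value
  before taking logs;
- dominance is declared by comparing the generalist's time average with
  the *pooled* specialist mean (the mean of the two specialists'
  averages), mirroring how the scans are summarized; crossovers are
  interpolated linearly in log population between adjacent grid points;
- each pulse always resets both $S$ and the environment, even if it
  arrives during an unfinished feast (rare at steady state).

## Known limitations

The invasion criterion is derived at the coarse-grained steady state with
constant $\Delta\tau$; the package evaluates it as stated also under
random intervals, where it describes long-run dominance but not the
temporal-average inversions — those are exactly the sparse-supply effects
the interval scans quantify. The cumulant expansion inherits the validity
range of the underlying scaling law (intermediate intervals, generalist-
dominant regime). One-environment specialists never dominate in the
simplex scans, matching the qualitative claim, but no exhaustive parameter
search is attempted. The analytic overlay curves for the interval scans
(a full derivation of $d$ and the large-interval corrections) are out of
scope; the scaling law enters only through fits.
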