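---
title: "Mean times to disease extinction under pulsed treatment: models, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean times to disease extinction under pulsed treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sispulse)
```

## The scientific problem

In a finite population an endemic disease eventually goes extinct by chance:
demographic fluctuations occasionally conspire to drive the infected count to
zero even when the deterministic dynamics predict stable endemicity.  The
mean time to extinction (MTE) is exponentially long in the population size,
and treatment programs shorten it.  This package quantifies that effect for
an SIS (susceptible–infected–susceptible) disease under *pulsed* treatment: at
moments governed by a schedule, a fraction $\kappa$ of all infected
individuals is cured at once and returns to the susceptible class.  Pulses
arrive either as a Poisson process with rate $\nu$ per year or periodically
at times $k/\nu$.  Three independent computational routes to the MTE are
implemented and cross-validated: exact Gillespie simulation, direct
master-equation solves, and a WKB (eikonal) large-deviation approximation.

## Models

**Constrained model** (one dimension).  The population is pinned at $N$; only
the infected count $I$ moves:

| event | jump | rate |
|---|---|---|
| infection | $I \to I+1$ | $\beta I (N - I)/N$ |
| recovery + death | $I \to I-1$ | $(\gamma + \mu) I$ |
| treatment pulse | $I \to I - \mathrm{round}(\kappa I)$ | $\nu$ (Poisson) |

A death of an infected is immediately compensated by a susceptible birth, so
recovery ($\gamma$) and turnover ($\mu$) merge into a single down-step.
Because the treated count must be an integer, $\kappa I$ is rounded: the
default `floor` rule keeps the integer part, so pulses *stop acting* once
$I < 1/\kappa$; the `ceil` rule always removes at least one infected.  This
threshold is not a numerical nuisance but a real mechanism with visible
consequences (see the fixed-dose experiment below).

**Full model** (two dimensions).  $S$ and $I$ move separately; births arrive
at the constant rate $\mu N$ (so the mean population is $N$ with
fluctuations), deaths are per-capita at $\mu$, infection is
$\beta S I / N$ with the fixed normalization $N$, recovery $\gamma I$, and a
pulse moves $\mathrm{round}(\kappa I)$ individuals from $I$ to $S$
(conserving $S + I$).

The basic reproduction number is $R_0 = \beta/(\gamma+\mu)$; under pulsed
treatment the mean per-capita removal rate gains $\kappa\nu$, giving
$R_T = \beta/(\gamma + \mu + \kappa\nu)$.  The mean-field endemic state
$x^* = 1 - 1/R_T$ exists iff $R_T > 1$; the implementation checks this
threshold against the mean-field balance directly.

Throughout, examples use a generic slowly spreading disease with
$\beta = 2$, $\gamma = 0.8$, $\mu = 0.2$ per year ($R_0 = 2$), chosen so all
regimes are reachable at desk-scale population sizes.

## The WKB machinery

Writing the quasi-stationary distribution as $P(x) \sim e^{-N s(x)}$ with
$x = I/N$ turns the master equation into a Hamilton–Jacobi problem with

$$H(x, p) = \sum_r w_r(x)\left(e^{p \cdot r} - 1\right),$$

where $w_r$ are the scaled channel rates and $r$ the scaled jumps, and
$p = \partial s/\partial x$ the momentum conjugate to $x$.  For the
constrained model

$$H = \beta x (1 - x)(e^{p} - 1) + (\gamma + \mu)x(e^{-p} - 1)
  + \nu\left(e^{-\kappa x p} - 1\right),$$

with the analogous six-term Hamiltonian for the full model (the pulse term is
$\nu(e^{\kappa x (p_s - p_x)} - 1)$).  The treatment exponent uses the
*linearized* bulk jump $-\kappa x$ in normalized units: the pulse channel is
continuous in $x$ and acts at arbitrarily low prevalence, in contrast to the
rounded master equation.  This linearization is what makes the theory a
*small-$\kappa$, moderate-$N$* approximation; its breakdown at large $N$ is
quantified below and is one of the package's substantive findings.

Fixed points of the characteristic flow
$\dot x = \partial H/\partial p,\ \dot p = -\partial H/\partial x$:

* disease-free state $(0, 0)$;
* endemic state $(x^*, 0)$ (momentum zero: the distribution peaks there);
* the *fluctuational die-out* state $(0, p_f)$ with $p_f < 0$ solving
  $\beta(e^{p}-1) + (\gamma+\mu)(e^{-p}-1) - \nu\kappa p = 0$.  Without
  treatment $p_f = -\ln R_0$; the equation is strictly convex with a root at
  zero, so the negative root is unique whenever $R_T > 1$ and is found by
  bracketed root-finding to $10^{-15}$.

The optimal path to extinction is the zero-energy heteroclinic from the
endemic state to the die-out point; its action
$s = \int \sum_i p_i\, dx_i$ sets the exponential scale of the MTE via
$\tau \approx B\, e^{N s}$.

### Path solver

`optimal_path()` discretizes the characteristic equations on
$t \in [-T, T]$ with second-order central differences, pins the boundary
nodes to the fixed points, and solves the stacked nonlinear system by damped
Newton iteration with an analytic sparse Jacobian.  Numerical choices:

* $T$ is set from the slowest linearization eigenvalue $\lambda$ at either
  endpoint so that $e^{-\lambda T} < 10^{-8}$, capped to $[5, 200]$ years.
  When Newton stalls (the basin can be sensitive to the truncation length) a
  short retry ladder of $T$ multiples runs before continuation in $\kappa$
  from the untreated problem.
* 1601 nodes by default; after convergence the mesh is doubled until
  $\max |H| \le 10^{-6}$ along the path (energy is an a-posteriori error
  gauge: the continuous path has $H \equiv 0$).  The action converges at
  the expected second order in the mesh spacing.
* The initial guess interpolates the endpoints with a logistic profile.  In
  four dimensions a plain interpolation is not enough: the full-model guess
  embeds the constrained zero-energy branch ($s = 1 - x$, $p_s = 0$, $p_x$
  from the branch), after which Newton converges in a handful of iterations
  across the whole treatment range.
* The action integral uses composite Simpson weights on the time
  parametrization, which stays well-defined when full-model coordinates are
  non-monotone.

For the constrained model the zero-energy manifold gives $p(x)$ as the root
of a scalar equation, so the action is also available as a one-dimensional
quadrature (`action_quadrature()`), machine-accurate and fast.  It serves as
an independent cross-check of the path solver (they agree to $\sim 10^{-6}$)
and as the per-cell engine of the quasi-stationarity map.

### Asymptotics and prefactor

`action_asymptotic()` implements the expansion
$s(\kappa) = s_0 + \kappa s_1 + O(\kappa^2)$ with
$s_0 = \ln R_0 - 1 + 1/R_0$ and the linear response
$s_1 = \nu \int x p \, dt$ along the untreated path, evaluated as a
quadrature over the closed branch.  The finite-difference slope of the
numeric action reproduces $s_1$ to $10^{-4}$ relative; the truncation error
grows from 0.05% at $\kappa = 0.01$ to a factor ~3 at $\kappa = 0.3$
(a warning fires beyond $\kappa = 0.2$).

`prefactor()` supplies the non-exponential factor $B$ in
$\tau = B e^{Ns}$ in three modes.  The analytic mode uses the matched
asymptotics of the one-dimensional chain,
$B = \sqrt{2\pi/N}\; R_T /\big((R_T - 1)^2 (\gamma + \mu + \kappa\nu)\big)$,
which reproduces the exact untreated chain to within 6% at $N \gtrsim 80$
and carries the policy dependence through $R_T$; under floor rounding at
moderate $N$ it underestimates treated MTEs (the inert-pulse region
$I < 1/\kappa$ adds to the true exponent), so for treated sweeps the
calibrated mode — one exact or simulated reference MTE recycled across the
sweep — is the recommended route, and is what cross-N log-MTE prediction
tests use.

## Master-equation routes

`build_generator()` assembles the sparse generator with the rounding rule
applied exactly; `mean_extinction_time_direct()` solves the first-passage
system over the transient states.  A subtlety worth recording: the direct
linear solve silently loses all accuracy once the MFPT exceeds roughly
$10^{13}$ years, because the transient block's smallest pivot falls below
double-precision resolution (the computed values can even go negative).  The
function warns in that regime, and `quasi_stationary_distribution()` provides
the stable alternative: uniformized power iteration
$v \leftarrow v + Q^{\mathsf T} v / \Lambda$ involves only non-negative
additions and multiplications, so the far tail of the quasi-stationary
distribution retains full *relative* accuracy down to $10^{-300}$, and the
decay rate is read off as the absorption flux
$\lambda_1 = (\gamma+\mu)\pi(1) + \nu \sum_{I:\,\mathrm{round}(\kappa I)=I}\pi(I)$
without cancellation.  This route was validated against a 60-digit
arbitrary-precision solve of the same chain ($\ln \tau$ agrees to four
decimals at a point where the double-precision direct solve is off by 0.8).

`evolve_distribution()` integrates $\dot p = Q^{\mathsf T} p$ with a stiff
solver, conserving mass to $10^{-8}$; it reproduces the exponential-decay
law (absorbed mass $\approx 1 - e^{-t/\tau}$) in the quasi-stationary regime
and the rapid drain of probability into the absorbing state when $R_T$ is
barely above one.

## Simulation

The Gillespie core is compiled code with explicit xoshiro256++ streams:
realization $i$ of master seed $m$ uses stream $\mathrm{splitmix64}(m, i)$,
so ensembles are bit-reproducible across platforms, order-independent, and
*paired* across policies — two ensembles sharing a seed share demographic
randomness realization-by-realization, which is how the schedule comparison
achieves matched budgets.  Periodic pulses are handled exactly: the
exponential clock is capped at the next pulse time (memorylessness makes the
cap exact), and the pulse fires deterministically.  Runs are censored at
`t_max` (default $10^4$ years); censored realizations are excluded from
moments, with a warning above 1% censoring.

What the simulator emulates is the model, not a real surveillance data set:
no seasonality, age structure, imperfect treatment uptake, reporting noise,
or spatial structure.  Passing cross-route checks therefore demonstrates the
internal consistency and numerical correctness of the three routes on this
model family, not epidemiological realism.

## Study fixtures used by the checks

* **Rare-but-simulable fixture.**  $\kappa = 0.05$, $\nu = 4$, $N = 50$:
  the exact extinction exponent $\ln(\tau/B) \approx 8.7$, so extinction is
  a rare event on the relaxation scale yet one Gillespie extinction costs
  only $\sim 3 \times 10^5$ events.  Here the simulated mean matches the
  exact MFPT within statistical error and the extinction-time coefficient of
  variation is 0.98 (exponential tail).
* **Schedule comparison.**  $N = 50$, ceil rounding,
  $\kappa \in \{0.02, 0.04, 0.06\}$, $\nu \in \{2, 4, 8, 12\}$, $n = 2000$
  paired realizations per cell.  Ceil rounding is deliberate: at this
  population size the floor rule's threshold $I < 1/\kappa$ silences small
  pulses near extinction and confounds the scheduling question with the
  rounding artifact.  With every pulse active, randomly scheduled treatment
  beats the periodic schedule in *all* twelve cells (aggregate paired
  z-score ≈ 15): random schedules occasionally deliver rapid-fire pulse
  sequences that extinguish the infection before it can relax back, which a
  periodic schedule never does.  Under floor rounding the ordering still
  holds wherever the endemic state exists and pulses remain active at it,
  and *reverses* in the supercritical-decay regime ($R_T \le 1$), where
  evenly spaced pulses waste none of the budget — both regimes are covered
  by the test suite.
* **Prehistory fixture.**  Full model, $N = 500$, $\kappa = 0.35$,
  $\nu = 2$ ($N s \approx 5.3$): extinction frequent enough to pool 5000
  extinct realizations in seconds.  The time-weighted occupancy of the last
  five years before extinction, binned over $(S/N, I/N)$ on a $40 \times 40$
  grid, has its ridge within two bin widths of the optimal path — the
  most probable route to extinction is visible in raw simulation data.
* **Fixed-dose experiment.**  Dose rate $C = \kappa\nu$ held fixed while
  $\kappa$ varies ($N = 200$, exact solver).  Under floor rounding the MTE
  drops by more than 20 natural-log units from $\kappa = 0.02$ to
  $\kappa = 0.4$ at $C = 0.2$: given a fixed annual treatment supply, few
  large campaigns beat many small ones, partly because small pulses round to
  nothing near extinction.  Ceil rounding removes that handicap and is never
  slower at matched $(\kappa, C)$.

## Findings and known limitations

Two findings from the validation work deserve emphasis because they bound
the theory's domain of validity.

**Sub-linear growth of $\ln \tau$ in $N$.**  The WKB estimate predicts
$d \ln \tau / dN = s$.  The exact chain obeys this locally at moderate $N$,
but at fixed $(\kappa, \nu) = (0.05, 4)$ the measured slope over
$N \in [300, 1500]$ is only ~0.05 against a numeric action of 0.120, with
$\ln \tau$ visibly concave (e.g. $\ln\tau = 35.61$ at $N = 300$,
computed by the decay-rate route and confirmed in 60-digit arithmetic).  The
discrete bulk-pulse channel admits extinction routes made of *bursts* of
pulses — $k$ pulses in quick succession cost only $\sim k \ln(k/\nu\Delta t)$
in log-probability while removing a fixed *fraction* per pulse, so their
total cost grows like $\ln N$, not $N$.  The linearized-exponent Hamiltonian
cannot see this route.  Consequently the WKB MTE is an intermediate-$N$
approximation for pulsed (bulk-jump) treatment, increasingly conservative as
$N$ grows; the acceptance suite records this honestly as a failing slope
comparison rather than hiding it.

**Constrained versus full model.**  At $\mu/\gamma = 0.25$ the full model's
extinction action is substantially smaller than the constrained one
(0.106 vs 0.193 untreated; ratio ~1.8 across the treatment range), because
population-size dips open a cheaper extinction route that the constrained
model forbids by construction.  This is confirmed independently by direct
MFPT solves of the full two-dimensional master equation at small $N$, whose
$\ln\tau$ slope matches the full-model action, not the constrained one.  The
two models agree on thresholds, fixed points and qualitative treatment
response (the constrained action responds to treatment roughly twice as
fast), but their exponents differ whenever demographic turnover is
non-negligible; the constrained model should be read as an upper envelope.

Other limitations: the analytic prefactor is small-$\kappa$/untreated-grade
(use the calibrated mode otherwise); the quasi-stationarity map covers the
constrained model only; periodic schedules have no Markov generator, so the
master-equation routes apply to Poisson scheduling (periodic pulses are
simulation-only); and there is no Floquet machinery, tau-leaping, spatial or
age structure by design.

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes every headline
quantity above from scratch — closed-form recoveries, tiny-chain oracles,
the treated action by all three formulas, the decay-rate route, the
simulation cross-check, both scheduling and dose experiments, the
prehistory ridge distance and the quasi-stationarity margin — and writes
them to JSON.  The test suite (`testthat::test_dir("tests/testthat")`)
checks the same science at fixed seeds, including the two deliberately
failing comparisons discussed under Findings.
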