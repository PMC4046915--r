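---
title: "Periodic enzyme forcing in E. coli central carbon metabolism: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Periodic enzyme forcing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`oscimet` simulates an extended kinetic model of *Escherichia coli* central
carbon metabolism: glycolysis, the pentose phosphate pathway, and the two
gluconeogenic reactions phosphoenolpyruvate synthase (PPS) and
fructose-1,6-bisphosphatase (FBP).  Mass balances for 18 metabolites follow

$$\frac{dC}{dt} = S\,r(C, P, e) + F - \mu C,$$

where $S$ is the 18 x 32 stoichiometric matrix, $r$ the vector of kinetic
rate laws with parameter set $P$, $F$ a constant feed (non-zero only for
extracellular glucose), and $\mu C$ a first-order dilution of every pool
into biomass at the specific growth rate $\mu$ = 2.78e-5 s^-1 (a 0.1 h^-1
chemostat).  Each reaction rate carries a dimensionless enzyme-level
multiplier $e_j/\hat e_j$ with nominal value 1, so every rate is linear in
its own enzyme level; "enzyme level 2" means twice the nominal catalytic
capacity.  Units are mM and seconds throughout; the command-line interface
accepts horizons in hours and converts.

Co-metabolites (ATP, ADP, AMP, NAD(H), NADP(H)) are held at their nominal
concentrations as constants rather than integrated, because the simulations
run over hours rather than the seconds-scale transients the source model
was fitted to.  Extracellular glucose *is* a state: it obeys a chemostat
balance with constant feed and washout at $\mu$, so uptake is ultimately
feed-limited on long horizons.  That choice matters scientifically -- it is
why a 50% step in the glucose uptake system (PTS) barely moves PEP at
steady state (the chemostat clamps the sustained uptake flux), and it keeps
an 8-hour simulation from silently exhausting the medium.  The PTS rate law
is expressed per reactor volume in the source parameterization; the loader
carries a calibrated conversion factor (`pts_scale`, about 65, the ratio of
cell specific weight to biomass density) so that the flux entering the
intracellular balances is on the cytosolic scale.

### Gluconeogenic reactions and top-down calibration

The kinetic constants of the 30 core reactions are transcribed from the
published source model.  The two gluconeogenic additions are modelled as
irreversible Michaelis-Menten steps with literature Michaelis constants
(PpsA: K_m,pyruvate = 0.083 mM; Fbp: K_m,FDP = 0.015 mM).  Their maximum
rates are not taken from any publication; they are assigned by a top-down
calibration at load of the shipped parameter file and cached in it:

1. each gluconeogenic reaction is given a nominal futile-cycle flux of 1%
   of the glucose uptake flux (on glucose, *pps* and *fbp* are weakly
   expressed, so a small but non-zero recycle is the realistic regime);
2. the r_max of PPS and FBP are solved from their rate-law shapes at the
   nominal state;
3. the r_max of PK and PFK are scaled up by the same flux so that every
   mass balance still closes (PPS/PK and FBP/PFK form the two futile
   cycles).

Finally the exact steady state of the calibrated system is located by
damped Newton iteration (residual below 1e-12 mM/s) and stored in the
parameter file with 17 significant digits, so that loading the file
reproduces a true steady state to well below the 1e-6 mM/s acceptance
tolerance.  `build_ccm_network()` reruns this whole calibration from the
raw constants; a test asserts it reproduces the shipped file.

## Forcing waveforms

An `enzyme_profile` describes one enzyme's level over time:
$e(t) = h + A\cos(\omega t + \varphi)$ with bias $h = 1$, or the square
wave $h + A\,\mathrm{sign}(\cos(\omega t + \varphi))$ (50% duty cycle), or
a constant.  Expression bounds default to 1/20 and 20 times nominal --
strong-promoter overexpression on the high side, tight repression on the
low side.  A symmetric unclamped cosine with $h = 1$ cannot simultaneously
approach 20x and stay above 1/20, yet optimal profiles do ride near the
upper bound; the package therefore *clamps* the evaluated waveform to
`[e_min, e_max]` (a rectified cosine).  The conservative alternative --
restricting amplitudes so the raw wave stays inside the bounds -- is
available by setting `A_max = min(e_max - 1, 1 - e_min)` in the
optimizers.  Clamping is the default because it is the only reading
consistent with both the stated bounds and profiles that saturate near
them.  Constant profiles are deliberately *not* clamped: knockouts (level
0) and 100-fold overexpression are expressed as constants outside the wave
bounds.

Enzymes added on a plasmid on top of the native copy (by default the
producers GAPDH and PFK) keep a floor of 1.0: induction can only add to
native expression.  The light-circuit program couples members to a single
physical input: induced members share $\omega, \varphi$; repressed members
(RPPK) carry the inverted wave $h - A\cos(\omega t + \varphi)$.

## Simulation

`simulate_network()` integrates the forced system with LSODA and samples a
uniform reporting grid (default 1 s).  The shipped model runs through a
compiled C right-hand side registered with deSolve; a pure-R evaluator
implements identical semantics (a test asserts pointwise agreement to
1e-12) and serves toy networks.  States are clipped at zero inside rate
evaluation to absorb solver noise; integrations that produce
concentrations below -1e-6 mM abort.  Default tolerances are rtol 1e-8,
atol 1e-10 mM; a tolerance sweep and reporting-grid refinement are both
asserted to move the total-PEP integral by less than 1e-4 and 1e-6
relative, respectively.

"Total PEP" is the trapezoid time integral of the PEP concentration over
the horizon (mM.s); every reported gain is a ratio of such integrals to
the unforced baseline, which makes the gains invariant to whether one
thinks of them as integrals or time averages.

## The step-test screen

`step_test()` holds one enzyme at a constant multiple (default 1.5) of its
nominal level, finds the new steady state, and reports the PEP ratio; the
screen flags enzymes with more than a 2% change in either direction
(production-decreasing enzymes flag too -- most flagged enzymes decrease
PEP).  "New steady state" is computed by damped Newton iteration first,
falling back to relaxation integration in 10-hour chunks (capped at 100
simulated hours) when Newton leaves the basin; the returned point must
satisfy a 1e-8 mM/s residual.  Flagged enzymes are ranked by effect size,
ties broken alphabetically.

## Optimization

The dynamic problem maximizes total PEP over amplitude, frequency and
phase of one wave per cluster enzyme, subject to path constraints at every
reporting point.  PEP is constrained to the absolute 1-10 mM window
reported for physiological variability; pyruvate, ribose-5-phosphate,
erythrose-4-phosphate and glucose-6-phosphate get a 10-fold band centred
geometrically on their nominal steady states, mirroring the 10-fold PEP
treatment (the experimental fold-change bounds behind these metabolites
are not published numerically, so the symmetric 10-fold band is this
package's choice, overridable via `constraints`).  Frequency is searched
over periods from 5 minutes (implementable gene-expression switching) to
one period per horizon; amplitudes up to 40 (beyond the clamp span,
flattening the wave towards a square); phases over the full circle.

The objective landscape is only piecewise smooth (clamped waves) and the
optimum rides the PEP ceiling: the unconstrained system could raise
average PEP more than tenfold, so virtually all of the interesting search
happens on the constraint boundary.  The search is accordingly
gradient-free and feasibility-aware:

* **Structured rays.** A deterministic amplitude line search along
  synchronized "push" rays -- producers cresting while
  production-decreasing enzymes trough, amplitudes scaled together -- at
  several trial periods.  Ray directions come from a cheap constant-step
  probe of each cluster enzyme.
* **Screen, then polish.** Every start (rays, a three-level factorial for
  problems of three or fewer variables, and seeded Latin-hypercube
  points) is evaluated once; the best start of each period family is then
  polished with Nelder-Mead under an exact penalty (1e4 mM.s per mM of
  summed worst violations), and polishing restarts from the incumbent
  while the evaluation budget (default 2000 simulations) lasts.
* **Feasible selection.** The best feasible points of the whole evaluation
  history are re-verified at fine solver settings (a coarse reporting grid
  can miss a constraint peak between points); marginally infeasible
  candidates are backed off by shrinking amplitudes a few percent.  The
  reported optimum is feasible within 1e-6 mM at the fine settings, and
  the unforced baseline is always an admissible fallback, so a reported
  gain is never below 1 when the baseline is feasible.

The time-invariant control (`optimize_static()`) replaces waves by
constant levels in [0, 20], with growth-essential enzymes restricted to
[0.25, 20].  The essential list (RPPK plus the biosynthetic drains SER,
SYN1, SYN2, MURSYNTH, TRPSYNTH, METSYNTH, G3PDH, DAHPS, PDH) is stored in
the parameter file and configurable; the same list guards `knockout()`.
The light-circuit optimizer shares one frequency and phase across members
by default (`coupling = "circuit"`); because the published description
does not say whether the members' waves were tuned jointly or separately,
the independent mode is also provided.

All randomness derives from the `seed` argument; given a seed, every
result is deterministic.  The structured rays and their polishes do not
depend on the seed at all, which keeps the reported gains stable across
seeds.

## The toy fixture

`make_toy_network()` builds a linear irreversible Michaelis-Menten chain
with constant influx, optional branch, and dilution, whose steady state
solves node-by-node as a quadratic -- a closed form the test suite checks
the numerical machinery against.  It emulates the structural features the
solvers rely on (saturable kinetics, dilution, branching) but none of the
biology: no allosteric regulation, no moiety coupling, no feed limitation.
Tests passing on the toy network therefore validate the numerics, not the
physiology; the shipped model's checks (steady-state closure, the screen's
flagged set, the knockout response) carry the scientific weight.

## Problem sizes and budgets

The shipped analyses use an 8-hour horizon.  Searches simulate on a
60-second reporting grid at rtol 1e-6 and re-verify reported optima on a
5-second grid at rtol 1e-8.  The nine-enzyme optimization uses 10 starts
within a 2000-evaluation budget; single-enzyme runs use 400 evaluations;
the pair screen reduces further (the ranking, not the absolute optimum,
is its product).  These sizes were chosen so a full analysis runs on a
laptop in minutes while leaving the reported optima stable to grid and
tolerance refinement.

## Known limitations

* Co-metabolite feedback (e.g. ATP drain under strong overexpression) is
  absent by construction; gains under extreme programs are accordingly
  optimistic.
* The transcription/translation dynamics of the light circuit are not
  modelled; the induced waveforms stand in for them.
* Single shooting with a gradient-free polish makes no global-optimality
  claim; reported optima are the best feasible points found under the
  stated budget, and a collocation-based optimal-control treatment could
  find better ones.
* The gluconeogenic futile-cycle flux (1% of uptake) and the 10-fold
  constraint bands are modelling choices where the sources give no
  number; both are configurable and both choices are deliberately
  conservative.
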