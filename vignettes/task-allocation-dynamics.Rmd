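---
title: "Social-learning dynamics of task allocation: model and methods"
author: "colonygames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Social-learning dynamics of task allocation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonygames)
```

## The model

A colony of `N` workers repeatedly faces two collective tasks. Each worker
`i` carries a behavioural strategy — a point on the 2-simplex
`(x_i, y_i, z_i)`, `x + y + z = 1` — giving the fractions of time spent on a
*homeostatic* task X (say thermoregulation), a *thresholding* task Y (say
brood care or defence), and inactivity. At every time step the population is
randomly partitioned into `K = N/n` games of `n` players. A game's collective
efforts `Sx = sum(x)`, `Sy = sum(y)` produce a group benefit that is shared
equally:

    B = (1/n) * B_X(Sx) * B_Y(Sy)

The two benefit factors couple *multiplicatively*: a colony that
thermoregulates perfectly but abandons its brood earns nothing. Costs are
individual and additive across tasks, `C(x, y) = C_X(x) + C_Y(y)`, so a
member's payoff is `B - C(x_i, y_i)`.

Learning is social: after payoffs are realized, the next population is formed
by sampling `N` role models with replacement, with probability proportional
to `exp(alpha * payoff)` (a softmax over the whole population — synchronous
Wright–Fisher resampling; a pairwise Fermi-imitation variant is available via
`learning_control(update = "imitation")`). Each agent then mutates with
probability `mu`: both free traits are perturbed by Gaussian noise of
standard deviation `sigma` and the pair is Euclidean-projected back onto the
feasible triangle.

## Functional forms and their parameters

The qualitative shapes are fixed by the biology; the exact forms used here
are the package's defaults and are pluggable through `register_shape()`:

* `B_X(S) = max(0, b1*S + b2*S^2)` — clamped quadratic. `b1 > 0` scales how
  rewarding the task is; `b2 < 0` makes it homeostatic (over-investment
  harms; the clamp keeps benefits non-negative), `b2 >= 0` makes it a
  maximizing task.
* `B_Y(S) = [tanh(beta*(S/n - w)) + tanh(beta*w)] /
  [tanh(beta*(1 - w)) + tanh(beta*w)]` — a normalized sigmoid in the
  per-capita effort `S/n`, anchored so `B_Y(0) = 0` and `B_Y(n) = 1`, with
  inflection at `S/n = w` and slope `beta`. Small `w` means the task needs
  little collective effort before it pays; `beta -> 0` degenerates to a
  linear ramp.
* `C_T(e) = c_T * e^k` with `k` in (0, 1] — marginally decreasing costs
  (tasks get easier with practice).

Default learning parameters are `n = 5`, `alpha = 2`, `mu = 0.01`,
`sigma = 0.005`, `T = 30000` steps, and a desk-scale population `N = 100`.

### Calibrating the cost scale

The cost parameters have no canonical published values, so they are fixed
once by a calibration exercise: the package's defaults must place four
reference environments (at `beta = 3`, `b2 = -6`: `b1 = 16, w = 0.3`;
`b1 = 23, w = 0.25`; `b1 = 28, w = 0.3`; `b1 = 30, w = 0.2`) in their
expected behavioural regimes — full inactivity, branching, uniform partial
activity, and bistable full activity/inactivity respectively. A joint sweep
of `(c_X, c_Y, k)` over the adaptive-dynamics layer and 30 000-step
simulations selected `c_X = c_Y = 0.6`, `k = 0.65`. With these defaults the
simulated steady state at `b1 = 23, w = 0.25` allocates its active workforce
close to 0.3/0.7 between the two tasks, the two low-`b1` environments are
inviable from uniform or inactive-leaning initial populations, and the
`b1 = 30, w = 0.2` environment is bistable. These values were fixed before
the acceptance analyses were frozen and are not revisited per experiment.

## Behavioural regimes and how runs are classified

`classify_run()` works on the final 10% of a trajectory (the steady-state
window). Window snapshots are pooled and clustered on the inactivity trait
`z` (1-D Gaussian mixtures, BIC model choice among 1–3 components, via
mclust), then clusters closer than 0.2 in `z` or holding under 10% of the
population are merged — thresholds that clear the `sigma = 0.005` mutation
noise floor by two orders of magnitude, so a mutation-blurred monomorphic
population is never mistaken for branching. Persistent multi-cluster
structure (70% of window snapshots) is *branching*; otherwise the window
mean of `z` decides: above 0.95 fully inactive, below 0.05 fully active,
in between uniform partial activity. A window whose mean `z` still moves by
more than 0.1 is reported `"unresolved"` instead of being force-labelled.

`classify_environment()` repeats this from three canonical initial
populations (active-leaning blob at (0.45, 0.5), inactive-leaning blob at
(0.02, 0.02), uniform on the simplex): full inactivity must hold from every
start; active and inactive outcomes from opposite-leaning starts mark the
bistable regime; otherwise the majority wins, with the agreement share
reported.

## The adaptive-dynamics layer

For a monomorphic resident `(x_r, y_r)`, the invasion fitness of a rare
mutant is its expected payoff in a group of `n - 1` residents minus the
resident's payoff in a pure-resident group; it vanishes identically at
mutant = resident. The selection gradient is computed by central finite
differences (step `1e-5`, one-sided at the feasibility boundary, with a
Richardson step-halving check attached). `find_singular()` damps a Newton
iteration on this gradient from a lattice of starting residents, deduplicates
roots within `1e-4`, and classifies each root by the standard multivariate
second-order conditions: the mutant Hessian of invasion fitness decides local
invadability, the Jacobian eigenvalues of the gradient map decide convergence
stability; convergence-stable + invadable is an evolutionary branching point,
convergence-stable + uninvadable an ESS. `predicted_region()` uses these
roots — and, when no interior attractor exists, projected-Euler integration
of the gradient flow from the canonical starts — as a fast analytic
stand-in for simulation-based classification; the two routes agree on over
80% of a random environment sample (see the test suite).

## Efficiency layer

The social optimum maximizes one game's mean member payoff over the full
`2n`-dimensional joint allocation (members need not be equal — branching
steady states are themselves asymmetric). The optimizer is differential
evolution, best/1/bin with `CR = 0.7`, `F = 0.5`, population 15x dimension,
five restarts by default and a Nelder–Mead polish, with member-wise
projection onto the feasible triangle; the best symmetric allocation is
reported alongside as a diagnostic lower bound. Relative colony efficiency —
the price of anarchy — is the steady-state population mean payoff (final-10%
time average) divided by the optimal mean payoff, clamped to [0, 1] for
reporting; the social efficiency deficit is the raw difference
`optimal - achieved`. Cells whose optimum is non-positive are flagged
undefined rather than dropped.

## What the stochastic engine can and cannot reproduce at desk scale

Two quantitative findings of the underlying theory deserve an honest
caveat, because they shape what passing tests mean.

**Branching is real but slow at small N.** At an evolutionary branching
point, trait variance grows at rate `~2*alpha*lambda*Var^2` (`lambda` = the
leading mutant-Hessian eigenvalue) while Wright–Fisher drift removes it at
rate `Var/N`. With `N = 100`, `mu = 0.01`, `sigma = 0.005` the mutation–drift
equilibrium variance sits roughly two orders of magnitude below the level at
which disruptive selection outruns drift, for every benefit/cost shape in the
default family (`lambda` peaks around 1–5). Desk-scale simulations therefore
show the *attractor structure* of the branching regime — the population
parks at the active branch's allocation — but not a persistent split into
coexisting active and fully idle sub-populations within 30 000 steps; runs at
`N = 2500` show the variance takeoff, followed by a sweep of the lazy branch
rather than stable coexistence under these forms. Quantities tied to the
*position* of the active branch (its 0.3/0.7 task split) are reproduced;
quantities tied to the *coexistence structure* (a lazy branch resting ~0.4
of the time in the `b2 = -4` branching environment) are not, and the
corresponding checks in the test suite are expected to fail at desk scale.

**Concave costs make the inactive corner locally absorbing.** With
`k < 1` the marginal cost of the first unit of effort is unbounded, so a
fully inactive population can never re-nucleate activity, and an
active-leaning initial population can retain partial activity even in
environments classified inviable. Full inactivity "from every initial
condition" is reproduced from uniform and inactive-leaning starts; from a
strongly active start the population settles at a residual-activity state
instead, and the corresponding acceptance check is likewise expected to
fail under the default forms.

## The synthetic-data layer

`make_fixture()` generates the populations used across the test suite —
monomorphic, bimodal (an active mode plus fully idle workers),
uniform-on-the-simplex, and noisy blobs at the mutation noise floor. They
emulate the *geometry* of real steady states (tight clusters, branch
separation on `z`, Dirichlet-flat initial conditions) but none of the
temporal correlation or payoff feedback of a live run, so tests built on
them validate the measurement machinery (clustering, classification,
ratios), not the dynamics; the dynamics are tested by the simulation-level
properties (neutrality, absorption, determinism, oracle equivalence) and by
the regime checks above.

## Numerical choices

Finite differences use `h = 1e-5` (the payoff surfaces are smooth away from
the clamp kink and the `e^k` boundary singularity; one-sided differences are
used within `h` of the boundary). The Newton solver tolerance is `1e-8`,
deduplication radius `1e-4`, classification tolerance `1e-5` on
second-order eigenvalues. Flow integration uses projected Euler with maximum
step 0.01 and stalls below `1e-7` gradient norm. The efficiency ratio treats
optima below `1e-12` as undefined. All experiment drivers derive per-run
seeds deterministically from one user seed; identical seed and configuration
reproduce trajectories bitwise.

Problem sizes used in the shipped tests — `N` of 50–100, horizons of
10 000–30 000 steps, 25-cell concordance samples, 101-point optimizer grid
oracles — were chosen so the whole suite exercises every regime in a few
minutes on a laptop while keeping every stochastic check at least an order
of magnitude away from its decision boundary.

## Known limitations

* The exact published benefit/cost formulas are not public; all quantitative
  statements are conditional on the default family above. Every form is
  pluggable via `register_shape()` should the canonical ones become
  available.
* Task-Y benefit amplitude is fixed at 1; sub-system M1 (task Y plus
  inactivity alone) is then dominated by costs at the default scale and is
  uniformly inviable — consistent with the absence of branching in that
  sub-system, but without the richer region structure the full model shows.
* No spatial or network structure: the population is well-mixed by
  assumption.
* Cluster detection caps at three branches.
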