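---
title: "Ensemble kinetic modeling of metabolic networks with massdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble kinetic modeling of metabolic networks with massdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented in `massdyn`, the modeling
assumptions behind each module, and the numerical decisions made where the
underlying methodology leaves room for interpretation. Code chunks are
illustrative and not evaluated when the vignette is built.

## 1. The modeling idea

Kinetic models of metabolism are usually assembled from enzyme-specific
rate laws whose parameters come from scattered in vitro assays, which makes
them laborious to build and hard to keep self-consistent. `massdyn` takes
the opposite route: every net reaction follows *elementary mass-action
kinetics*,

$$v_j = k_{f,j}\Big(\prod_i x_i^{a_{ij}} - K_{eq,j}^{-1}\prod_i x_i^{b_{ij}}\Big),$$

with stoichiometric coefficients $a_{ij}, b_{ij}$, one forward rate
constant $k_{f,j}$, and one equilibrium constant $K_{eq,j}$. Irreversible
reactions are the limit $K_{eq} \to \infty$; the reverse term is dropped
symbolically rather than evaluated as a division by infinity. The system
dynamics are $\dot x = S\,v(x)$ with $S$ the stoichiometric matrix; fixed
("boundary") species have their rows clamped to zero.

The single free kinetic parameter per reaction is obtained by inverting the
rate law at one observed steady state $(v^{ss}, x^{ss})$:

$$k_{f,j} = \frac{v_j^{ss}}{\prod_i (x_i^{ss})^{a_{ij}} -
K_{eq,j}^{-1}\prod_i (x_i^{ss})^{b_{ij}}}.$$

This *pseudo-elementary rate constant* (PERC) folds unknown enzyme levels
and saturation effects into one lumped constant, chosen so the model
reproduces the snapshot exactly: the data point is the model's reference
steady state by construction. Two consistency conditions guard the
inversion: the denominator's sign must match the flux's sign (a flux may
only run down its thermodynamic driving force), and a zero flux leaves
$k_f$ unidentifiable — `compute_percs()` then assigns a configurable
default (0) with a warning and flags the reaction, rather than inventing a
value.

Thermodynamic quantities follow from the *mass-action ratio*
$\Gamma = \prod x^b / \prod x^a$: the disequilibrium ratio is
$\Gamma/K_{eq}$ and $\Delta G = RT \ln(\Gamma/K_{eq})$ with
$R = 8.314\times10^{-3}$ kJ/(mol K) and $T = 310.15$ K by default. Units
are molar and hours everywhere; `convert_flux_units()` maps fluxomics in
mmol/gDW/h to M/h via a cell density in gDW per litre.

## 2. Why an ensemble

A single fluxomics/metabolomics snapshot is noisy, and many flux and
concentration states are compatible with it. Instead of committing to one
parameterization, the package builds a population:

1. **Flux states** are sampled uniformly from the steady-state flux cone
   $\{v : S v = 0,\ lb \le v \le ub\}$ (measured fluxes can be pinned by
   degenerate bounds $lb = ub$).
2. **Concentration states** are sampled uniformly from the
   thermodynamically feasible polytope in log-concentration space: for
   each reaction carrying flux of sign $s$,
   $s\,(\ln K_{eq} - \sum_i (b-a)_i \ln x_i) \ge \epsilon$, intersected
   with a box around the reference state.
3. Every flux-by-concentration pair is PERC-parameterized into a
   **candidate model** whose sampled state is its exact steady state.
4. Candidates are **filtered**: each is perturbed (e.g. a 50% increase in
   the ATP utilization rate constant) and must reach a steady state
   through simulation; failures are recorded in a discard log, never
   silently dropped.
5. Survivors are **simulated** on a shared log-spaced time grid and
   quantities are **aggregated** per time point.

The headline aggregate in the examples is Atkinson's adenylate energy
charge $(\mathrm{ATP} + \mathrm{ADP}/2)/(\mathrm{ATP} + \mathrm{ADP} +
\mathrm{AMP})$, a 0–1 index of the cellular energy state.

## 3. Sampling machinery

Both samplers are *hit-and-run* Markov chains: from a strictly interior
point, draw an isotropic random direction, intersect the line with the
polytope to get the feasible chord, jump to a uniform point on the chord,
and emit every `thin`-th state (default `thin = 100`). Hit-and-run mixes
well on the low-dimensional, well-conditioned polytopes used here and
needs only constraint evaluations. The starting point is the Chebyshev
center (the center of the largest inscribed ball), found by a linear
program; a positive radius certifies a non-empty interior, and an empty
polytope is reported as such rather than sampled. Samples are
feasibility-asserted before being returned, and the sampler saves and
restores the global RNG state so seeded workflows compose predictably.

Flux sampling runs in nullspace coordinates: with equality-pinned
coordinates folded into the constraint matrix, every emitted sample
satisfies $S v = 0$ to $10^{-9}$ by construction, and pinned coordinates
are snapped to their exact values afterwards (the nullspace mapping
otherwise leaves $10^{-18}$-scale dust that would confuse downstream
sign checks).

Two quadratic programs support the samplers: `fit_fluxes()` finds the
steady-state flux vector closest to a set of measured fluxes (with a tiny
ridge on unmeasured fluxes so the optimum is unique), and
`adjust_concentrations_min()` projects an infeasible concentration vector
onto the feasible polytope with minimal squared displacement in
log-concentration space. `futile_cycle_inflate()` adds a stated fraction
of the net flux to both legs of an opposing irreversible pair, reflecting
proteomic evidence that both enzymes are active, without changing the net
flux state.

## 4. Enzyme modules

When regulatory detail matters, one net reaction can be expanded into a
*module* of elementary steps with explicit enzyme forms: uni-uni (2 or 3
steps), ordered bi-bi, and a two-state allosteric (MWC-style) variant
with a catalytically inactive T conformation. Because elementary rates
are linear in the enzyme forms at fixed ligand concentrations, the
module's internal steady state is a linear solve with the conservation
constraint $\sum \text{forms} = e_{total}$, and the net flux scales
linearly both in $e_{total}$ and under a joint rescaling of all $k_f$.
`fit_rate_constants()` exploits that linearity: an evenly split seed is
rescaled analytically to hit the target flux to machine precision, and
the Haldane relation (path equilibrium constants multiply to the net
$K_{eq}$) is enforced by eliminating the last path step's $K_{eq}$ rather
than by a penalty, so it holds exactly. Optional $K_m$/$k_{cat}$
constraints are handled by a log-parameterized quasi-Newton refinement.

`merge_module()` swaps a fitted module for its host reaction, setting
form concentrations to the internal steady state at the host's reference
ligands, and verifies that the module reproduces the replaced reaction's
reference flux — so the merged model keeps the host's reference steady
state, and the enzyme's conservation pool appears in
`conserved_pools()`. The merge is reversible via `unmerge_module()`.

## 5. Numerical choices

- **Integration**: `deSolve::lsoda` (adaptive stiff/non-stiff switching)
  with an analytically derived Jacobian (`stats::D` on the symbolic rate
  laws), `rtol = 1e-8`, `atol = 1e-12`. Concentrations are clipped at
  zero during evaluation; undershoot beyond $100\,\mathrm{atol}$ is an
  error rather than silently repaired.
- **Steady states**: the criterion is
  $\|\dot x\|_\infty < \max(\mathrm{atol}_{ss},\ \mathrm{rtol}_{ss}
  \|v\|_\infty)$ with defaults $10^{-9}$ and $10^{-6}$. Strategies:
  expanding-horizon integration, a damped Gauss-Newton in
  log-concentration variables on the conserved-pool-augmented residual
  (log variables keep states positive; the solver therefore needs a
  strictly positive start), and a hybrid that integrates briefly and
  polishes with Newton. This damped Newton stands in for more elaborate
  homotopy/continuation root finders; at the problem sizes used here it
  converges in a handful of iterations.
- **Stability**: eigenvalues of the Jacobian projected onto the
  stoichiometric subspace — conserved pools contribute structural zero
  modes that are removed by reduction, not by thresholding. The ensemble
  filter instead uses the operational criterion from the workflow:
  perturb and re-reach a steady state within a $10^4$ h horizon;
  integration failures (e.g. ATP depletion driving concentrations
  negative) count as unstable.
- **Conserved pools**: an exact rational reduced-row-echelon
  left-nullspace of the stoichiometric matrix over *non-fixed* species,
  scaled to minimal integers. Fixed species are clamped, not conserved,
  which is why they are excluded. Floating-point SVD nullspaces are used
  only where exactness is not required (flux-space sampling bases).
- **LP/QP**: Chebyshev centers via `boot::simplex`; quadratic programs
  via `pracma::quadprog`. The Chebyshev center is not unique on
  slab-shaped polytopes, so code and tests rely only on feasibility and
  the maximal radius.

## 6. Interpretation decisions

Where the methodology is stated loosely, the package commits to these
readings:

- **"Up to 80% deviation"** is interpreted in linear concentration space:
  $(1-d)\,x_{ref} \le x \le (1+d)\,x_{ref}$ with $d = 0.8$
  (`bound_mode = "deviation"`). The alternative reading — symmetric
  decades around the reference — is available as
  `bound_mode = "magnitude"`, where $d$ counts orders of magnitude
  ("within an order of magnitude" corresponds to $d = 1$).
- **Confidence bands** are per-time-point normal-theory intervals,
  $\bar q(t) \pm 1.96\,s(t)/\sqrt{n}$, over the stable candidates on the
  shared grid; medians and quartiles are empirical with the default
  linear interpolation. No simultaneous (family-wise) band is attempted.
- **Energy charge** uses Atkinson's definition with the ½ weight on ADP.
- **Zero-flux reactions** receive `kf = 0` by default (with a warning and
  a flag) since the data carry no information about them; the toy
  glycolysis fixture's adenylate kinase — structurally forced to zero net
  flux by the AMP balance — instead gets a directly assigned capacity so
  the adenylate pool stays dynamically connected, while candidates keep
  `kf = 0` so their sampled states remain exact steady states.
- **Perturbations** are single-instant changes: multiplicative by
  default (a factor on a reaction's $k_f$ or a species concentration),
  absolute on request. State trajectories stay continuous across the
  instant unless a species value itself is the target.

## 7. The bundled generators, and their limits

`make_linear_chain()` builds an open source-to-sink pathway with
randomized equilibrium constants and disequilibrium ratios strictly
inside (0, 1), so every step keeps a forward driving force and the
PERC-parameterized reference state is exact. `make_toy_glycolysis()`
builds a compact glycolysis analogue: hexokinase and
phosphofructokinase (PFK) consume ATP, a lumped lower-glycolysis step and
pyruvate kinase regenerate it, an ATP-utilization load drains it,
fructose bisphosphatase opposes PFK as a futile cycle, and adenylate
kinase connects ATP/ADP/AMP. Its flux state carries uptake $u$, a
futile-cycle fraction $f \in [0.15, 0.3]$, and load $(2-f)u$, with the
mass balances satisfied identically; reversible $K_{eq}$ values are
placed a randomized distance above the reference mass-action ratio so the
state is feasible by construction.

These generators are deliberately small (6–10 species): they exercise
every code path — boundary species, conserved pools, futile cycles, an
equilibrium-pinned reaction, reversible and irreversible steps — at desk
scale. They are not genome-scale reconstructions, and published
organism-specific numbers (stable fractions, enzyme activity
distributions) depend on external curated models outside this package's
scope; the workflow, not those numbers, is what is reproduced here.
Typical problem sizes used in the tests: 15 × 15 = 225 candidates,
$10^4$ hit-and-run samples for distributional checks, polytopes of 4–7
dimensions.

## 8. Interchange formats

Models serialize to a versioned JSON schema (concentrations molar, time
hours; `Keq = Inf` encoded as the string `"inf"`; unknown fields are
preserved through read/write cycles for forward compatibility; numbers
are written with 17 significant digits so doubles round-trip exactly).
`export_sbml()` writes SBML Level 3 Version 1 core with every kinetic law
as explicit MathML of the mass-action form and `kf`/`Keq` as local
parameters, so the exported file is self-contained for other simulators.
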