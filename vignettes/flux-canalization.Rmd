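---
title: "Flux-based auxin canalization: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux-based auxin canalization: models, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxcanal)
```

## The model and its assumptions

`fluxcanal` studies the flux-based hypothesis for PIN polarization: the PIN
concentration on a membrane face grows with the auxin flux through it. Cells
are nodes of an undirected tissue graph; geometry enters only through cell
volumes $V_i$ and membrane areas $S_{ij}$. There is no cell growth,
division, or spatial embedding beyond optional plotting coordinates, and no
concentration-based or hybrid PIN-allocation mechanism — those are
deliberately out of scope.

Three variants share the transport law
$J_{i\to j} = \gamma_D (a_i - a_j) + \gamma_A (a_i p_{ij} - a_j p_{ji})$:

* **full** (`rhs_full()`): $\dot a_i = \alpha_{ai} - \beta_{ai} a_i -
  \tfrac{1}{V_i}\sum_{j\sim i} S_{ij} J_{i\to j}$ and
  $\dot p_{ij} = h(J_{i\to j}) + \rho_0 - \mu p_{ij}$. Basal insertion
  $\rho_0$ is allowed here only.
* **extended** (`rhs_extended()`): adds cytosolic PIN $P_i$ with production
  $\alpha_p$, degradation $\beta_p$, insertion $\lambda P_i h(J)$ and
  recycling $\mu p_{ij}$. With $\alpha_p = \beta_p = 0$ the per-cell total
  $P_i + \tfrac{1}{V_i}\sum_j S_{ij} p_{ij}$ is a first integral, term by
  term, and our implementation preserves it to the last bit (the insertion
  and removal terms are computed once and reused with opposite signs).
* **slow** (`rhs_slow()`): the slow-PIN reduction on a *regular* tissue
  (all $V_i$ equal, all $S_{ij}$ equal, $W = S/V$) with diffusion dropped:
  $\dot a_i = \alpha_{ai} - \beta_{ai} a_i + \sum_{k\sim i}(a_k p_{ki} -
  a_i p_{ik})$, $\dot p_{ij} = \lambda \bar P\, \Phi(J_{i\to j}) - \mu
  p_{ij}$ with $\bar P = \alpha_p/\beta_p$ and $J_{i\to j} = a_i p_{ij} -
  a_j p_{ji}$. It refuses non-regular tissues; the full/extended variants
  accept per-cell $V_i$, $S_{ij}$. We keep the active-transport scale $T$
  explicit rather than silently normalizing it to 1; `normalize_params()`
  applies the $W$-normalization and the $\varepsilon$-scaling
  ($\alpha_p/\varepsilon$, $\beta_p/\varepsilon$, $D_0\varepsilon$) on
  request, under which the capacity $c$ is invariant.

Membrane PIN is stored per **ordered** adjacent pair — $p_{ij}$ and
$p_{ji}$ are independent state variables (two per undirected edge) — because
the insertion law is written per directed membrane face, and because the
steady-state complementarity ($p^*_{ij} = 0$ or $p^*_{ji} = 0$ on every
membrane) is what turns equilibria into orientation graphs. That
complementarity is also why $\rho_0$ is excluded from the slow variant: a
basal insertion floor would keep both faces positive and destroy the
orientation structure.

Units are consistent working units supplied by the user; there is no
conversion layer. All defaults below are dimensionless conventions
($\kappa = J_{\text{ref}} = 1$ for the quadratic response, matching
$\Phi(x) = x^2$), not physical measurements.

## The response family

`response_function()` implements rectified kinds — zero for $J \le 0$,
nondecreasing beyond: linear $\kappa x/J_{\text{ref}}$, quadratic
$\kappa (x/J_{\text{ref}})^2$, hill $\rho x^n/(\theta^n + x^n)$, power
$\rho x^n$, and bounded custom functions. Boundedness is the decisive
property: bounded responses give globally defined solutions (and admit
steady *loops*); unbounded ones admit finite-time blow-up of membrane PIN
and, at steady state, force loopless sink-rooted forests. The rectified
quadratic is $C^1$ with derivative $0$ at $J = 0$, so Jacobians of the slow
variant are well defined; `rf_deriv()` returns that one-sided derivative
for every kind, and the analytic slow-variant Jacobian uses it.

## What the scenario generators emulate — and what they do not

All inputs are programmatic; nothing is downloaded. `make_grid()` builds
4-neighbour lattices (optionally with ±10% seeded jitter on volumes and
areas, the "non-regular cells" robustness setting), `make_line()` builds
open or periodic cell files, `random_in_tree()` samples uniform labelled
trees (Prüfer decoding) with a uniform root, and `random_state()` draws
seeded nonnegative states. The three study scenarios bundle the printed
parameter sets:

* `scenario_grid_patches()`: 8 × 11 grid, $\alpha_a = 0.1$ except two
  3-cell patches at $2.1$, $\beta_a = 5$, $\lambda = 5$, $\mu = 0.1$,
  quadratic response. The patch *placement* is not prescribed beyond "two
  groups of 3 cells"; we default to rows 3 and 6, columns 4–6
  (configurable), and all topology checks are position-insensitive
  (forest-ness, out-degrees), never cell-level.
* `scenario_sink_line()`: 20 cells, only cell 10 degrades auxin
  ($\beta_{a,10} = 0.1$); the uniform production $\alpha_a = 0.1$ is a
  documented assumption (flagged in the scenario notes), as the original
  experiment does not print it.
* `scenario_source_line()`: 20 cells, source at cell 1 with
  $\alpha_{a1} \in \{0.9, 3.1\}$, $\alpha = \beta = 0.1$,
  $\lambda = \mu = 0.01$, $c = 1$. The printed setup satisfies
  $\beta > \mu/2$; we record that as a scenario property, not a model
  constraint.

These scenarios emulate idealized tissues: identical cells, no growth, no
boundary fluxes, quadratic response everywhere. Passing tests on them shows
the *mathematical* behaviour of the model under its own assumptions — they
say nothing about measured auxin levels in real meristems, heterogeneous
cell geometry beyond ±10%, or mechanisms (influx carriers, concentration
sensing) the model omits.

### Initial conditions

The original experiments do not print initial states, so each scenario
documents its own choice, derived from linear stability of the all-isolated
configuration $E_0 = (\alpha_{a}/\beta_{a}, 0)$. $E_0$ is asymptotically
stable for the quadratic response, so infinitesimal jitter decays and no
vein ever forms: a membrane face adjacent to a cell at auxin level $a$
amplifies only above the nucleation level
$p > \mu\beta_p/(\lambda\alpha_p a^2)$. Accordingly:

* the source-line scenarios start from background auxin with a small
  *forward-polarized* PIN loading (0.2 on faces pointing away from the
  source, seeded 1% jitter, reverse faces empty) — the basipetal priming a
  primordium provides. 0.2 clears the source-adjacent nucleation level
  (≈ 0.012 for $\alpha_{a1} = 0.9$) while faces between background cells
  (level ≈ 1) still decay, and it also keeps PIN alive long enough
  (lifetime $1/\mu = 100$) for the canal to propagate cell by cell;
* the grid scenario uses uniform $U(0, 0.3)$ initial PIN: above the
  patch-cell nucleation level (≈ 0.11 at $a = 0.42$), far below the
  background-cell one (≈ 50 at $a = 0.02$), so canals nucleate at the
  patches and nowhere else;
* the sink-line scenario starts at its exact spanning-tree equilibrium with
  1% relative jitter. The leading eigenvalues there are numerically
  $\pm\mu i$, so the trajectory orbits the equilibrium — the sustained
  oscillation this experiment is known for — rather than converging.

## Steady-state machinery

`extract_orientation()` reads the orientation off a converged state with a
*relative* threshold $10^{-6}\max(1, \max p)$, so the rule survives unit
rescaling; membranes with both faces above threshold raise an error naming
the offending edges (they contradict the slow-model equilibrium structure).
`classify_topology()` computes degrees, sinks, sources, cycles and the
sink-rooted-forest property, and issues a verdict that is strictly a
**falsifier**: no sink, a cycle, or out-degree > 1 certifies instability of
the underlying equilibrium (quadratic response); "necessary conditions met"
never certifies stability — spectral claims always come from
`jacobian_stability()`, which uses the analytic Jacobian for the slow
variant and central finite differences otherwise, classifying by
$\max\mathrm{Re}(\lambda)$ against a tolerance `tol_eig` (default
$10^{-8}$; between $\pm$`tol_eig` the verdict is "marginal").

`solve_sink_tree()` evaluates the exact in-tree solution by one post-order
pass of subtree production sums $A(i)$: $a_i = 1/(c\,A(i))$ off the root,
$a_{i_0} = A(i_0)/\beta_{a,i_0}$, $p = c\,A(i)^2$ on the out-edge. The sums
grow along every path into the root, so auxin *decreases* into the sink —
the flux runs against the gradient and the sink sits in a depleted
neighbourhood. `sink_tree_state()` embeds the solution as a model state;
its slow-variant residual is zero to rounding, which the tests assert.

For the sink-driven *dynamics* fixtures the capacity is fixed at $c = 1$
but $\lambda, \mu$ are free (steady states depend on them only through
$c$). The PIN time scale decides whether the tree equilibrium attracts:
with $\lambda = \mu = 1$ the computed spectra have
$\max\mathrm{Re}(\lambda) \approx +0.1..0.3$ (the equilibrium repels and
long-run agreement with the formulas would be unobservable), while
$\lambda = \mu = 0.1$ gives $\max\mathrm{Re}(\lambda) \approx -0.08$ across
the random-tree ensemble. The fixtures therefore use
$\lambda = \mu = 0.1$: slow PIN turnover relative to auxin turnover, the
same ordering as every printed scenario.

`solve_source_chain()` eliminates membrane PIN from the chain steady-state
equations to a flux recursion
$J_k^2 - (\alpha + J_{k-1})J_k + \beta/c = 0$ (with $\alpha_0$ in place of
$\alpha + J_{-1}$ at the source). The upper root at each step is the branch
the dynamics select; the recursion seeds a damped Newton polish of the full
nonlinear system (continuation in chain length), with 10 seeded multistart
attempts before the solver reports `"no_solution"` — a status, not an
exception, since the steady system is polynomial with multiple branches and
genuine non-existence (a weak source cannot sustain an arbitrarily long
with-gradient vein: the discriminant eventually fails). Key consequences:

* **Regimes.** $a_k = 1/(cJ_k)$ along the vein body, so the source cell
  sits above background ($\alpha/\beta$) iff
  $J_0 = \tfrac12(\alpha_0 + \sqrt{\alpha_0^2 - 4\beta/c}) \le
  \beta/(c\alpha)$: weak sources give regime A (auxin above background,
  increasing along the vein), strong sources regime B (below background,
  decreasing). `classify_regime()` tests the inequality chains over the
  vein *body*: the terminal cell of any finite chain is a sink whose
  balance $a_n = (\alpha + J_{n-1})/\beta$ makes it accumulate regardless
  of regime, so including it would mislabel every regime-B vein. Bare
  numeric profiles are classified exactly as given. The degenerate constant
  profile at background satisfies both chains and is reported as A with a
  `degenerate` flag (deterministic tie-break).
* **Regime map.** `regime_map()` classifies, by default, the longest
  admissible vein not exceeding `n` edges (`shrink = TRUE`): insisting on
  exactly `n` would relabel the entire short-vein part of the A region as
  failure. Points with $\alpha_0 \le \alpha$, or with no vein at all, are
  labelled `"other"`. The map is invariant under
  $(\alpha, \alpha_0, \beta) \to s(\alpha, \alpha_0, \beta)$,
  $c \to c/s$ — the scaling that fixes the steady-state equations
  ($\lambda$ and $\mu$ enter only through $c$) — and the tests verify this
  by direct recomputation.
* **Source-strength condition.** The printed inequality
  "$\alpha_0 \ge 2\beta c > \alpha$" is typographically ambiguous between
  $2\beta c$ and $2\beta/c$ (the two readings coincide at $c = 1$, where
  all printed experiments live). `source_condition()` exposes both readings
  as a documented predicate; no solver hard-codes either. The solver's own
  existence requirement is the discriminant condition
  $\alpha_0 \ge 2\sqrt{\beta/c}$.

## Numerical choices

* **Integrator.** `deSolve`'s lsoda (stiff-capable, adaptive), run in
  segments with a convergence check ($\|\dot x\|_\infty <$ `conv_tol`,
  default $10^{-8}$) between segments and root-triggered termination for
  blow-up. Default tolerances `rtol = 1e-8`, `atol = 1e-10`; the
  exactness tests tighten them to `1e-11`/`1e-13`. Identical inputs give
  identical trajectories — the integrator holds no hidden randomness, and
  every random draw in the package flows through an explicit seed that
  never touches the caller's RNG state.
* **Blow-up detection** is numerical, never a proof: the run is flagged
  divergent when the largest membrane PIN crosses a threshold (default
  $10^6$) while still accelerating upward; the escape time is extrapolated
  as $\hat\delta = t + p/\dot p$, exact for the locally quadratic growth
  $\dot p \sim K p^2$ that unbounded responses produce near escape. The
  global-vs-finite-time dichotomy for unbounded responses is what licenses
  reading this signature as divergence. The estimate is required (and
  tested) to move < 5% under 100× threshold and 10× tolerance changes.
  The cut-off mode (`run_with_cutoff()`) instead clamps PIN at `p_max`
  after each segment — reproducing the behaviour of earlier simulation
  studies that imposed bounds, not the model's intrinsic dynamics — and by
  construction never reports divergence.
* **Oscillation detection** inspects the last 20% of the run (default):
  a variable oscillates when its amplitude exceeds `osc_tol` (relative to
  its scale) while its windowed mean drifts by less than a tenth of that
  amplitude. This is a heuristic flag for orbiting an equilibrium; it makes
  no claim about periodicity.
* **Degenerate inputs.** Single cells and empty edge sets are valid
  tissues; `p_max = 0` turns active transport off; `n = 0` chains return
  the isolated source; empty orientations classify as (vacuous) forests
  with the all-isolated verdict left at "necessary conditions met".

## Problem sizes in the test suite

The suite runs in a few minutes on one CPU: the grid experiments use the
full 8 × 11 tissue (five seeds, plus one non-regular run with
$D = 10^{-3}$ under the full variant); sink-driven exactness uses 20 random
in-trees of 4–12 nodes integrated to $\|\dot x\|_\infty < 10^{-10}$ and
compared at $10^{-6}$ relative; the slow–fast reduction compares the
20-cell weak-source line over $\varepsilon \in \{0.1, 0.01, 0.001\}$ with
$D_0 = 0.1$; conservation checks use 100 random states on a 3 × 3 grid.
These sizes match the printed experiments where sizes are printed, and are
stated here as the package's own choices elsewhere.

## Known limitations

* Stability verdicts from topology are necessary conditions only; the
  spectral analysis is numerical (finite-difference for non-slow variants)
  and silent within `tol_eig` of the imaginary axis — the sink-line
  equilibrium, with leading eigenvalues numerically on the axis, is
  classified "marginal", and its sustained oscillation is established by
  simulation, not spectra.
* Blow-up times are estimates attached to a detector, not certified escape
  times; a pathological solution that decelerates above the threshold
  would be (correctly) left unflagged.
* The chain solver's multistart explores finitely many branches of a
  polynomial system; `"no_solution"` means none was found under
  continuation plus multistart, not a non-existence proof.
* The closed-form machinery (in-trees, chains, regimes) assumes the
  quadratic response and the slow-PIN variant; for other responses those
  entry points do not apply and only simulation is available.
* No tissue growth, no geometry, no auxin influx carriers, no
  concentration-based PIN allocation, no continuum/PDE limit.
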