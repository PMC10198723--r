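---
title: "Methods: coupled cooperation-risk dynamics in riskcoev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled cooperation-risk dynamics in riskcoev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskcoev)
```

## The model

A well-mixed infinite population plays a threshold public-goods game in
randomly sampled groups of size $N$. Every player holds an endowment $b$;
cooperators contribute $c$ ($0 < c < b$). If at least $M$ group members
cooperate ($1 < M < N$), everyone keeps their remaining endowment. Otherwise
the group fails collectively with probability $r$ and all members lose what
they kept. With $j_C$ cooperating co-players, the focal payoffs are

$$P_C = b\,\theta(j_C + 1 - M) + (1-r)\,b\,[1 - \theta(j_C + 1 - M)] - c,
\qquad
P_D = b\,\theta(j_C - M) + (1-r)\,b\,[1 - \theta(j_C - M)],$$

with $\theta$ the Heaviside step ($\theta(0) = 1$: a group that exactly
meets the target succeeds). Averaging over $j_C \sim \mathrm{Bin}(N-1, x)$,
the payoff advantage of cooperation collapses to the closed form

$$f_C - f_D = \Gamma(x)\, r\, b - c, \qquad
\Gamma(x) = \binom{N-1}{M-1} x^{M-1} (1-x)^{N-M},$$

because cooperation only changes the group outcome in the pivotal
composition $j_C = M - 1$ (probability $\Gamma(x)$), where it converts a
risked endowment $rb$ at cost $c$; in every other composition it is a pure
loss of $c$. Both routes are implemented — `payoff_difference()` (closed
form) and `average_payoffs()` (binomial enumeration) — and the test suite
holds them to each other at $10^{-12}$ over a thousand random parameter
draws, so neither is trusted on its own.

The risk is a state variable coupled to the strategy dynamics:

$$\varepsilon \dot x = x(1-x)\,[\Gamma(x)\,r\,b - c], \qquad
\dot r = r(1-r)\,K(x),$$

where $\varepsilon > 0$ sets the relative speed of strategy updating
(it rescales $\dot x$ only, so equilibria are $\varepsilon$-independent) and
the kernel $K$ is either

* **linear**: $K(x) = u(1-x) - x$, $u > 0$ the rate at which defection
  drives risk up, cooperation driving it down at relative rate one; or
* **sigmoid** ("exponential"): $K(x) = \frac{1}{1+e^{\beta(x-T)}} -
  \frac{1}{1+e^{-\beta(x-T)}}$, risk falling once cooperation exceeds the
  threshold $T \in (0,1)$ with steepness $\beta \ge 0$.

The sigmoid is evaluated internally as $-\tanh(\beta (x-T)/2)$, an algebraic
identity that is overflow-safe up to $\beta \sim 10^6$ and covers the
steplike $\beta \to \infty$ regime. $\beta = 0$ is accepted but flagged:
strategies then have no effect on the risk. A `custom_feedback()` hook takes
any $(x, r) \mapsto \dot r$ function; only the linear and sigmoid families
carry analytic equilibrium support.

## Equilibrium structure

The logistic factors make all four corners of $[0,1]^2$ fixed points. On the
high-risk edge $r = 1$, fixed points sit at the roots of $\Gamma(x)\,b = c$:
$\Gamma$ is unimodal with mode $(M-1)/(N-1)$, so there are two roots
$x_1^* < x_2^*$ when $c/b$ is below the peak, a double root at tangency, and
none above. `find_threshold_roots()` brackets each monotone branch with
`uniroot` at tolerance $10^{-15}$. The interior point sits at
$x = u/(1+u)$ (linear) or $x = T$ (sigmoid) with
$r^* = c / (\Gamma(x)\,b)$, and exists only while $r^* < 1$ strictly; at
$r^* = 1$ it merges with a boundary root and is reported once, as the
boundary point. The catalogue therefore holds 4, 5 (tangency), 6, or 7
points, and every returned point is checked to annihilate the vector field
to $10^{-10}$.

Stability comes from the analytic Jacobian: at an interior point the risk
row's diagonal entry vanishes and the trace reduces to
$x(1-x)\,\Gamma'(x)\,r^* b / \varepsilon$, so the interior point is stable
exactly when the interior $x$ lies right of the mode of $\Gamma$. That gives
the closed-form Hopf thresholds

$$u_c = \frac{M-1}{N-M} \quad\text{(linear)}, \qquad
T_c = \frac{M-1}{N-1} \quad\text{(sigmoid)},$$

independent of $\varepsilon$, $b$ and $\beta$ (for $\beta > 0$).
`hopf_threshold_numeric()` re-derives them by Brent root-finding on the
trace, and the suite requires agreement to $10^{-10}$ across all
$(N, M)$ with $2 \le M-1 < N-1 \le 12$. Eigenvalue real parts within
$10^{-9}$ of zero are labelled `center_hopf` (conjugate pair) or
`marginal_degenerate` (single zero, e.g. the coincidence
$x_2^* = u/(1+u)$) rather than being forced to stable/unstable; resolving
the degenerate cases is delegated to simulation, not to a center-manifold
expansion.

The regime partition of the $(u, c/b)$ and $(T, c/b)$ planes follows from
the same quantities (`classify_region()`): `bistable_interior` above the
threshold with an interior point, `hopf_line` on the threshold,
`defection_only` below it or when no alternative stable point exists, and
`bistable_boundary` when only $(x_2^*, 1)$ with $x_2^*$ left of the kernel
balance point accompanies the tragedy point $(0,1)$ — which is stable for
every admissible parameter combination, in both families.

## A degenerate Hopf point: what the package actually finds

The interior eigenvalues are a purely imaginary pair on the threshold, so a
Hopf bifurcation is the natural reading, and sustained oscillations are
indeed observed there. The standard next step — the first Lyapunov
coefficient $\ell_1$ from the cubic normal form, computed by
`first_lyapunov_coefficient()` — has a surprise in store:

* evaluated with fourth-order central differences at step $h$, the formula
  returns a value that shrinks by a factor of $\sim 16$ every time $h$ is
  halved — the signature of pure $O(h^4)$ truncation error around an exact
  zero. The function therefore Richardson-extrapolates estimates at $h$ and
  $h/2$; the extrapolated $\ell_1$ is $\sim 10^{-10}$ for both families at
  the reference game, and symbolic evaluation of the same normal-form
  formula confirms the coefficient is exactly zero across every parameter
  set tried. (The machinery is not at fault: on a textbook supercritical
  oscillator it recovers the known negative coefficient.)
* simulation agrees with the degenerate picture. On the threshold,
  trajectories settle onto constant-amplitude orbits whose amplitude is set
  by the initial condition — a continuum of neutrally stable cycles, i.e.
  center-like local dynamics, not a unique attracting limit cycle. Slightly
  below threshold the interior spiral is unstable and trajectories escape to
  $(0,1)$; slightly above, they spiral into the interior point. No interior
  cycle exists off the threshold, so there is no amplitude-versus-parameter
  scaling law to measure, and `cycle_amplitude_ladder()` honestly reports
  fixed points on every rung.

The practical consequences: oscillatory coexistence of cooperation and risk
is confined to the measure-zero threshold manifold; the amplitude observed
there is a memory of the starting state; and any claim that the emerging
cycle is "stable" in the attracting sense is not supported by the cubic
normal form — deciding the fate of the center under higher-order terms
would require a fifth-order (second Lyapunov quantity) analysis, which is
beyond what this package asserts. `detect_attractor()` still labels the
threshold oscillation `limit_cycle`, in the descriptive sense of a sustained
periodic orbit with a measured period and amplitude.

## Numerical choices

* **Integrator**: `deSolve::ode` with `method = "vode"` (BDF when stiff),
  $\mathrm{rtol} = \mathrm{atol} = 10^{-10}$, `maxsteps = 5e5`. Small $\varepsilon$ makes the
  strategy equation fast; vode handled every regime tried, including
  $\varepsilon = 0.01$ trajectories that pin to two boundaries at once
  (where lsoda's stiffness switching failed). Output lands on a uniform
  grid of about four points per time unit (capped at 20001), dense enough
  for peak detection at the observed periods ($\sim 6$–40 time units).
* **Containment**: the unit square is forward-invariant analytically; the
  numerical solution is required to stay within $10^{-9}$ of it, is clipped
  afterwards, and the clipped magnitude is kept on the trajectory object
  (`clip_magnitude`, `max_excess`) so boundary stickiness is visible.
* **Attractor calls**: terminal drift $\|(\dot x, \dot r)\| < 10^{-8}$ plus
  proximity ($10^{-4}$) to a catalogued point declares a fixed point; a
  cycle needs $x$-amplitude above $10^{-3}$ sustained over the last quarter
  of the run, at least 5 peaks separated by a refractory window of 1% of the
  analysis span, and successive peak heights varying by less than 5%.
  Horizons: 2000 time units by default, 1500–2000 in the test suite's
  trajectory checks, and an analysis window of at least 100 time units —
  anything shorter returns `undetermined` with a diagnostic rather than a
  guess.
* **Basin maps**: grid points start strictly inside the square at offsets
  $k/(R+1)$ (the boundaries are invariant sets) and use lighter settings
  ($t_{\max} = 1000$, tolerances $10^{-8}$) than single-trajectory work,
  because hundreds of runs are integrated and only the attractor identity
  matters. Maps are fully deterministic.
* **Parameter defaults**: the reference game $N = 6$, $M = 3$, $b = 1$,
  $c = 0.1$, $\varepsilon = 0.1$ with $u \in \{2, 2/3, 0.5, 4\}$ or
  $T \in \{0.5, 0.4, 0.2, 0.8\}$ ships as the eight presets; these are the
  canonical regime representatives for this game (bistable interior, Hopf
  line, defection only, bistable boundary). $\beta$ has no canonical
  published value; the presets use $\beta = 10$ — steep enough to be
  decisively nonlinear, far from the steplike limit — and the stability
  threshold in $T$ does not depend on it.

## What the tests do and do not show

The suite cross-validates closed forms against enumeration oracles, analytic
Jacobians against finite differences, analytic thresholds against trace-zero
continuation, and analytic stability labels against simulated attractors, on
top of property checks (containment, $\varepsilon$-invariance, determinism).
All of this concerns the idealised model: an infinite well-mixed population,
deterministic replicator dynamics, two strategies, one feedback loop, no
delays and no stochastic shocks. Passing tests say nothing about finite
populations (where demographic noise can kick the system across the basin
boundary), structured interactions, or real behavioural data. The boundary
$r = 1$ deserves particular caution: several catalogued equilibria sit on
it, and the logistic factor makes it sticky in finite precision — which is
why clipping is logged rather than silent.

## Known limitations

* The center-type degeneracy at the Hopf threshold is established
  numerically (symbolically at third order); the package does not compute
  second Lyapunov quantities, nor does it continue periodic orbits in
  parameter space.
* The degenerate coincidence $x_2^* = u/(1+u)$ is labelled, not resolved.
* Custom feedback kernels get trajectories, attractor detection and
  finite-difference Jacobians, but no analytic equilibrium catalogue.
* Phase portraits are utilitarian (direction field, equilibria,
  trajectories); no speed-coded flow rendering.
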