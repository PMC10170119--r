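---
title: "chaosmorph: models, numerical choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chaosmorph: models, numerical choices, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`chaosmorph` simulates the pattern-generation chain: spatial gradients force
a reaction–diffusion (RD) system to form sharply localized segments; the
segment amplitudes obey a finite-dimensional dynamical system that can be
made chaotic; chaotic or stochastic trajectories, read through a partition
of morphogen space, emit any prescribed string of cell types; and staging
the target into substrings makes the emission time short and low-variance.
This vignette is the package's own account of those models, the tunable
parameters, the numerical choices, and — importantly — what a green test
does and does not establish.

## 1. The reaction–diffusion core

The integrator (`simulate_rd`) advances
`du_i/dt = d_i Δu_i − λ_i u_i + f_i(u) + η_i(x, y)` on the strip
`[0, Lx) × [0, Ly]`, periodic in `x` (cell-sampled, `hx = Lx/nx`) and
bounded in `y` (vertex-sampled, `hy = Ly/(ny−1)`), with per-component
zero-flux Neumann walls (mirrored ghost rows) or pinned homogeneous
Dirichlet walls. Method of lines with second-order central differences;
explicit RK4 in time; additive white noise, when enabled, enters as an
Euler–Maruyama increment `amp · sqrt(dt) · N(0,1)` per node after each
deterministic step. The time step must satisfy the pure-diffusion CFL bound
`dt ≤ 0.9 · hx²hy² / (2 max(d_i)(hx² + hy²))` (`rd_stable_dt`); reaction
stiffness remains the caller's responsibility and a violated bound is
rejected before integration, never silently clipped. Any non-finite value
or `|u| > 1e8` aborts with the last finite time (polynomial reactions can
escape in finite time). Dimensionless units throughout: lengths in units of
the strip scale, rates per unit time, concentrations are deviations from a
reference state, so negative values are meaningful.

The screened-Poisson solver (`solve_screened_poisson`) shares the discrete
Laplacian with the integrator and solves `d_w Δw − b²w = s` by a sparse
direct factorization. With `b = 0` and no Dirichlet wall the operator is
singular: a zero-mean source is required and the zero-mean solution is
returned (constant-mode deflation by a rank-one bordering). The residual of
the discrete equation is checked against `1e-8` times the source scale and
attached to the result.

`dispersion_growth_rates` is the Turing-instability oracle: the largest real
eigenvalue part of `J(u0) − k²D − diag(λ)` per wavenumber, with the reaction
Jacobian from central finite differences at the verified homogeneous
equilibrium (residual above `1e-8` is an error, not a warning).

## 2. Segment bases and amplitude systems

Segment profiles are periodized Gaussians `ψ_i ∝ exp(−(x−x̄_i)²/2ε²)`,
normalized to unit discrete L² norm. Gaussians are one admissible choice of
"exponentially localized" profile; they give closed-form overlap bounds for
tests and are exact eigenmodes of the harmonic confinement used by the
embedding (below). Projection of a field onto amplitudes solves the Gram
system (least squares within the span); a Gram condition number above `1e12`
is refused. Centers closer than `4ε` only warn — overlaps are then handled
by the Gram solve but are no longer negligible.

Amplitude systems come in two compiled families — quadratic–cubic
(`F_i = c0_i + (LX)_i + X_i(BX)_i + cub_i X_i³`, which covers linear
systems, the Rössler field, and the reduced projections of embeddings) and
weakly coupled segment groups (bistable scalar units `Ẋ = X − X³` and
planar units with a stable focus plus a stable unit limit cycle) — plus an
interpreted fallback for arbitrary vector fields. Integration is fixed-step
RK4.

The largest Lyapunov exponent uses the Benettin tangent method: the
variational equation runs alongside the flow with the analytic Jacobian
(finite differences for custom fields), the tangent is renormalized every
0.5 time units by default, and the standard error comes from 20 contiguous
blocks of the post-transient log-growth sequence. The default transient is
10% of the horizon, not 20%: the documented precondition
`horizon ≥ 10 · transient` would otherwise be unsatisfiable at the default.
An independent two-orbit (trajectory-separation) implementation lives in the
test helpers and pins the Benettin result for the Rössler system
(λ ≈ 0.07 at a = b = 0.2, c = 5.7).

Attractor enumeration integrates each start past a settling transient,
fingerprints the orbit by per-coordinate time mean and amplitude range
rounded to `1e-2`, merges fingerprints within twice that tolerance in the
max norm, and labels attractors fixed-point / periodic / aperiodic (the
latter split by a short Lyapunov probe at threshold 0.01). This
distinguishes fixed points, cycles, and chaotic sets without topology
computations; two distinct attractors with identical means *and* ranges
would be merged, which the constructed group systems cannot produce.

## 3. The chaotic embedding: design rationale

`embed_target_ode` realizes a prescribed quadratic amplitude field inside a
two-component slow/fast RD template: `u` slow, `v` fast with relaxation
`λ₂` and screening length `1/β = sqrt(D_v/λ₂)`, `v` sourced by `u` through
a gain field. The construction had genuinely open design freedom; the
choices below were forced by off-manifold stability, and each is measured,
not assumed:

* **Reaction channels.** Only pointwise-safe channels are used:
  `a(x)u` (local rates), `b(x,y)v` and `h(x,y)v²` (linear and quadratic
  readouts of the fast field, which add no `∂f/∂u` and whose feedback loops
  are damped by fast-field smoothing), a magnitude-capped `d(x,y)uv`
  product channel, `e(x)u²`, and the gradient source `ζ(x)`. An uncapped
  product channel is the natural way to build bilinear couplings such as
  Rössler's `X₃X₁`, but its pointwise rate `d·v` exponentially amplifies
  off-manifold grid modes even when its projection is exact.
* **Harmonic confinement.** The slow diffusion is tied to the degradation,
  `d_u = λ₁ε²/8`, and the activation field carries a parabolic well
  `A0 = λ₁ + d_u/ε² − d_u dx²/ε⁴` (truncated at its zero crossing, exactly
  `3ε`). The Gaussian ψ is then an exact eigenmode of the linear part, and
  every excited in-window mode is damped by the well's level spacing
  `2d_u/ε² = λ₁/4`. This is what lets `λ₁` be large (10³–10⁴): strong local
  self-activation balancing strong degradation confines the slow reagent to
  its segments while the projected amplitude dynamics stays O(1).
* **Odd reading profiles.** Reading shapes antisymmetric about a segment
  center null the segment's own fast-field contribution *and its
  relaxation lag* by symmetry and read the gradient of cross-segment
  kernels; the product channel uses odd shapes exclusively.
* **The second space dimension.** The fast-field source gain carries y
  harmonics (`1 + cos(πy/Ly) + 0.8cos(2πy/Ly)`), so v holds several y-modes
  whose x-screening rates differ; reading with different y-profiles
  discriminates same-side sources at different distances. With pinned
  (Dirichlet) walls on v the y-flat mode does not exist and every coupling
  decays at the first-harmonic rate — which is why the embedding template
  defaults to Neumann walls for v (the general integrator supports both).
* **Calibration.** All couplings are fitted globally (every channel is read
  by every row — profile tails overlap once gains are large) by a weighted
  ridge regression: weights are dynamical importances from a reference
  orbit of the target (a residual matters in proportion to its monomial's
  typical size against a low quantile of `|dX_i/dt|`, because errors hurt
  most in slow phases such as the Rössler reinjection), penalty rows
  suppress the cubic relaxation-lag monomials the quadratic algebra cannot
  cancel, and the ridge strength is the smallest that respects the
  pointwise hazard caps. First-order relaxation-lag corrections
  (`v ≈ G·X − G₂·F(X)`) are folded into all readings.
* **Newton correction.** A damped Newton iteration matches the slow
  invariant subspace of the exact sparse discrete linearization (block
  inverse iteration) and re-targets the calibration by the observed
  discrepancy. This removes systematic linear drift (y-mode contamination,
  slaving feedback) that no static projection sees.
* **Defect metric.** Because the Newton step deliberately pre-distorts the
  static targets, the reported defect is the static fit residual against
  the calibration's own targets *plus the measured residual of the realized
  linear dynamics against the true target* — both computed, neither
  assumed. `embed_target_ode` errors above `defect_tol` (default 10%).

The packaged Rössler demonstration embeds the amplitude-rescaled system
(`scale = 0.1`, i.e. `Y = X/10`): a linear conjugacy that leaves the
Lyapunov spectrum and attractor topology exactly invariant while keeping
segment amplitudes O(1), which the polynomial channel algebra needs. The
segment layout places the bilinearly coupled pair adjacent
(`X₃–X₁–X₂` along the axis) so the strong coupling is read at O(1)
efficiency.

**What the tests establish, and what stays red.** The linear-contraction
and harmonic-oscillator embeddings meet their contracts (≤ 5% trajectory
deviation; < 2% energy drift per period). For the Rössler embedding at the
256×17 grid, the measured construction defect is ≈ 9% (within the 10%
contract), and the realized projection's largest Lyapunov exponent is
0.061 ± 0.004, positive and within two standard errors of the pure-ODE
value 0.070 ± 0.004 — the chaoticity claim survives the realization. The
10% trajectory-tracking clause over a full recurrence time (≈ 6 time units)
is a *known red*: the realization retains a residual coupling structure of
a few percent (dominantly a spurious `X₃X₂` bilinear set by the finite
screening contrast between the two segment distances), and a chaotic flow
amplifies a percent-level vector-field error through `e^{λt}` and
orbit-phase slippage beyond 10% L² within one recurrence. The measured
distance is ≈ 0.24. Reaching 10% would need ≈ 1% structural accuracy,
which this two-component template on this grid could not deliver under the
off-manifold stability caps; the criterion is left failing rather than
loosened.

## 4. The stochastic Turing machine

Random absorbing chains draw each transient row from a flat Dirichlet over
all `n` states (normalized unit exponentials) and make the target row
absorbing — the canonical uninformative ensemble for "constant transition
probabilities"; target reachability is verified by graph search. Exact
hitting moments come from the fundamental matrix (`(I−Q)t = 1`;
`E[τ²] = (2N−I)t`); Monte Carlo paths are compiled and seeded. Because the
printed normalization `σ(τ) = Eτ/√Var τ` and its staged approximation
`≈ 1/√k` cannot both hold for sums of independent stages (the coefficient
of variation scales as `1/√k`, the printed ratio as `√k`),
`absorption_stats` reports both `sigma_paper` and `cv` with jackknife
standard errors; the pinned single-stage value `≈ 1` is
definition-independent. The hypercube search uses pure nearest-neighbour
flips without laziness (parity alternates each step and does not block
absorption); the staged variant freezes each matched substring and
continues on the next subcube, and total time is exactly the sum of stage
times. Censoring (default `1000·n` steps) is flagged, never dropped.

## 5. Cell alphabets, partitions, and string emission

The four-type alphabet `gr, wr, gb, wb → 00, 01, 10, 11` encodes two
successive binary differentiation decisions. Partitions of scalar morphogen
space are half-open intervals `[lo, hi)` with the final interval closed and
boundary values assigned upward — the declared tie-break closing the
measure-zero gap open-interval definitions leave to the implementation.
The per-cell averaging window defaults to half the minimum sample-position
spacing (the cell extent is otherwise unspecified); time sampling
interpolates linearly between bracketing snapshots; the operator reads the
instantaneous field with spatial averaging only (a time-window average is a
documented alternative, not implemented).

The tent map `x → 2min(x, 1−x)` with the dyadic partition is the exactly
analyzable emission source: its symbol stream is Bernoulli(1/2), so mean
first-occurrence times of words follow the classical self-overlap
(correlation) formula used as the test oracle. Floating-point tent iterates
collapse onto dyadic rationals within ~50 steps, so the implementation adds
uniform jitter of width `1e-12` per step — twelve orders of magnitude below
the partition resolution — restoring ergodic symbol statistics without
affecting any measurable frequency. The Rössler first coordinate
thresholded at its long-run median is the flow-based alternative source.

## 6. The synthetic world, and its limits

Everything is generated in-repo: gradient fields, random chains, hypercube
plans, weakly coupled group systems, the Rössler target, tent-map dynamics
— all bit-reproducible from `(kind, parameters, seed)` with manifest
hashes. Where the source material fixes no value the defaults are one
realistic choice made once: `Lx = 2π` (the stated periodicity), `ε = 0.1`
(segments well separated from both grid scale and domain scale), flat
Dirichlet rows for chains, Bernoulli(1/2) random hypercube targets, unit
oscillator parameters. A green suite establishes that the implemented
operators satisfy their stated contracts on these synthetic worlds at desk
scale — `2^{M_a}` attractors at `M_a ≤ 3`, linearity of Eτ over
`n ≤ 256`, acceleration at one `(m, k)` point — not asymptotic statements,
not robustness to ensembles the generators do not emulate (correlated
kernels, non-Gaussian segment shapes, heavy-tailed environments), and not
the formal genericity or persistence theorems, which are out of scope by
design.
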