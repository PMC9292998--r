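---
title: "A channel-dipole model of rheotaxis: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A channel-dipole model of rheotaxis: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheodipole)
```

## The model and its assumptions

`rheodipole` treats a fish swimming in a two-dimensional channel as a finite
vortex dipole in potential flow, coupled in both directions to its
environment. The assumptions, in decreasing order of importance:

1. **Potential flow.** The fluid is inviscid and the flow around the swimmer
   irrotational except for an imposed, weakly rotational background profile.
   Boundary layers, wakes and any turbulence fluctuations are outside the
   model; the background shear parameter `eps` stands in for the
   *time-averaged* curvature of a real profile.
2. **Far-field dipole.** The swimmer's near field is not resolved: the dipole
   description is valid at distances large compared to `r0`, which requires
   `rho = r0/h << 1`. The constructor enforces `rho < 0.5` and warns above
   `0.2`.
3. **No inertia.** The swimmer responds instantaneously to the local flow:
   its velocity is the local advective velocity plus self-propulsion, its
   turn rate the local hydrodynamic turn rate plus lateral-line feedback.
   Transients driven by body elasticity or added mass are not described.
4. **No wall contact.** The drift closed forms are singular on the walls and
   the model says nothing about touching them; trajectory integration stops
   at a configurable wall-proximity band (`wall_delta`, default 1% of `h`).
5. **Linear circulation feedback.** The lateral line is summarized by a
   single gain `K` multiplying the circulation sensed over a rectangle of
   width `r0` along the body length `l`. Vision, vestibular and tactile
   pathways are deliberately absent.

## Evaluating the wall interaction

No-penetration at both walls requires an infinite lattice of image dipoles.
Writing the dipole as a complex velocity `q = u - iv = r0² v0 e^{iθ}/(z-z_f)²`,
the images fall into four families whose n-th members are `1/(a + bn)²`
lattices with `b = ±2ih`.

**Truncated series with analytic tail (reference route).** Summing `N` image
sets truncates an absolutely convergent series whose per-set terms decay like
`n⁻³`, so plain partial sums converge only like `1/N` — far too slowly for
the tolerances this package promises (with `N = 200` the bare sum still
carries ~10⁻³ relative error at the swimmer). Because each family is an
explicit `1/(a+bn)²` lattice, however, the tail from `N` to infinity has a
closed-form integral and derivatives, and Euler–Maclaurin summation

```
Σ_{n≥N} f(n) ≈ ∫_N^∞ f dn + f(N)/2 − f′(N)/12 + f‴(N)/720
```

is exact to `O(N⁻⁸)`. With the default `truncation_policy()` (`max_sets =
200`, tail correction on) the series is accurate to machine precision, and
the policy's `tol = 1e-10` (in units of `v0`) is checked against the next
Euler–Maclaurin term. The uncorrected sum remains available
(`tail_correction = FALSE`, and `wall_series_partial_sums()` for
diagnostics); its slow convergence and monotone per-set increments are
pinned in the unit tests rather than hidden.

**Closed form (cross-check route).** Using
`Σ_{m∈Z} 1/(ζ − 2ihm)² = (π/2h)² csch²(πζ/2h)`, the whole lattice sums to

```
q_w(z) = r0² v0 [ e^{iθ} (S(z−z_f) − 1/(z−z_f)²) + e^{−iθ} S(z−z̄_f) ],
S(ζ) = (π/2h)² csch²(πζ/2h),
```

with a removable singularity at the swimmer (`S(ζ) − 1/ζ² → −π²/12h²`). This
expression was derived independently for this package and is verified in two
ways: numerically against the tail-corrected series at scattered points, and
analytically — its de-singularized value at the swimmer reproduces the
`csc²`-form advective velocity exactly. The two routes are kept separate so
that each can serve as the other's oracle.

**Singularity policy.** Evaluation points within `1e-6·h` of the dipole or
any image are rejected with an error naming the point; no regularization is
applied, because the far-field model has nothing credible to say there.
Field grids additionally blank a disk of radius `r0` around the swimmer.

## Swimmer dynamics

The drift uses the closed forms, not the series: the advective velocity
(walls + background at the swimmer, self-singularity removed) and the
turn rate obtained from the velocity difference across the two constituent
vortices in the limit of small separation. The turn-rate sign structure is
physical: walls attract the heading toward the nearest wall
(`∝ cot(πy/h) csc²(πy/h) cos θ`), while the background shear always turns
the swimmer counter-clockwise in the upper half-channel and clockwise in the
lower, regardless of heading (`∝ (y/h − 1/2) cos²θ`).

`turn_rate_finite_dipole()` implements the finite-separation rule directly —
the two vortices at `r_f ± (r0/2) v̂⊥` sampling the series field — and is the
package's independent oracle for the closed form. A measurement worth
recording: the deviation between the two shrinks as `r0⁴` (error ratio 16
under halving), not the `r0²` one would expect from a generic symmetric
difference; the leading error term cancels for this field. The tests pin the
observed fourth-order behavior.

Because the channel vorticity is *linear* in `y`, the circulation over the
sensing rectangle equals its area times the vorticity at its centroid with
no approximation, so the linear-feedback closed form
`λ = K r0 l (8 U0 ε/h)(y_f/h − 1/2)` is exact within the model — the
quadrature oracle in the tests agrees to 1e-12.

## The planar system and its analysis

Cross-stream position and heading decouple from the streamwise coordinate.
Equilibria have `θ_f ∈ {0, π}` and `ξ` a root of

```
(π³/32) cot(π(ξ+½)) csc²(π(ξ+½)) = ±βξ,   β = α(1+κ)/ρ².
```

The left-hand curve is odd, strictly decreasing, has slope `−β* = −π⁴/32` at
the origin and diverges to `−∞` at the wall. Consequences exploited by the
code:

* **Root finding.** For upstream swimming the off-center roots exist iff
  `β > β*`, and then `g(ξ) = curve + βξ` has exactly one root in `(0, ½)`
  (`g′(0) > 0`, `g → −∞`). `find_equilibria()` brackets the sign change on a
  10⁴-point grid and polishes with `uniroot` at tolerance 1e-15, mirroring to
  negative `ξ`; bracketing is robust where derivative-based iteration near
  the wall singularity is not. For reference, the outer roots approach the
  wall like `½ − ξ* ≈ (16β)^{-1/3}` — at `β = 10⁴` they are still 0.019 from
  the wall, so "near the wall" is an asymptotic statement.
* **Exact threshold.** `beta_star()` returns the closed form `π⁴/32`; the
  numerical slope match and the sign change of `det A` under bisection are
  *tests* of that value, never its source.
* **Zero trace by construction.** Both diagonal entries of the linearization
  carry a factor `sin θ_f`, which vanishes at every equilibrium, so the state
  matrix is assembled with an exact zero diagonal and `classify()` treats a
  nonzero trace as a contract violation. Classification is by the sign of
  `det A` — saddle below, neutral center above — with determinants within
  1e-10 of zero reported as `"degenerate"` rather than forced into either
  class: the transition `β = β*` is a measure-zero boundary, not a third
  dynamical regime.
* **Frequency.** `sweeping_frequency()` returns `√(det A)` at the upstream
  centerline (exact) or the small-`ρ` form `(π²/2) ρ √(β/β* − 1)` when asked.
  Its oracle, `orbit_period()`, integrates a small-amplitude orbit and
  averages upward zero crossings of `ξ(t)` located by linear interpolation
  over ≥ 10 cycles — robust to solver step placement.

## Integration

No ODE-solver package is assumed by the environment, so the package carries
an embedded Dormand–Prince 5(4) pair with PI step-size control
(`solver_policy()`, defaults `rtol = 1e-8`, `atol = 1e-10`). The planar
center is neutral, so tight tolerances are the defense against spurious
amplitude drift; the 50-period boundedness test holds the orbit envelope to
1%. Wall-proximity events are localized by bisection on the step size to
~1e-12. Trial states outside the domain return `NaN`, which the controller
treats as a rejected step — the right-hand side is never evaluated on the
walls. The heading is integrated unwrapped and wrapped only for reporting.

One genuine model feature discovered in testing and worth knowing: the
cross-stream speed factor `1 − (π²ρ²/12)(3csc² − 1)` vanishes at a distance
of roughly `ρh/2` from either wall, so swimmers *stall* before reaching it.
With the default event band (1% of `h`) wall events therefore only occur for
`ρ` below about 0.02; this is wall repulsion in the model, not an integrator
artifact.

## Parameters that matter

| Parameter | Meaning | Units | Default / typical | Why |
|---|---|---|---|---|
| `rho` | dipole-to-channel ratio `r0/h` | — | 0.02–0.13 (presets) | far-field validity; `r0 ≈ 0.2 l` when only body length is known |
| `alpha` | shear-to-swimming ratio `U0 ε/v0` | — | 0–1 (presets) | sets the restoring shear torque |
| `kappa` | feedback gain `K r0 l` | — | 0–7 (presets) | from threshold-speed ratios, `U_c` ablated / intact = `1 + κ` |
| `beta` | `α(1+κ)/ρ²` | — | derived | sole stability parameter; threshold `π⁴/32` |
| `max_sets` | image sets summed | — | 200 | with tail correction, any `N ≥ ~30` is at machine precision |
| `tol` | series tail tolerance | `v0` | 1e-10 | checked against the next Euler–Maclaurin term |
| `rtol`, `atol` | solver tolerances | — | 1e-8, 1e-10 | neutral center: prevent amplitude drift |
| `wall_delta` | event band | fraction of `h` | 0.01 | closed forms singular at walls; contact out of scope |
| `grid_n` | root-bracketing grid | — | 10⁴ | resolves roots down to `½ − ξ* ≈ 0.02` (`β ≈ 10⁴`) |

## What the packaged fixtures are, and are not

`table1_presets()` ships nine literature-derived parameter ranges (point
estimates stored as points, ranges as intervals, unknown entries as missing
and never imputed; presets whose `alpha` came from intact-fish swimming
speeds are flagged). They are *constants for orientation and testing*, not
data pipelines: a green test against them establishes that the package
reproduces the arithmetic and the stability structure implied by those
ranges — for instance that recomputing `β` bounds from a row's `ρ`, `α`, `κ`
reproduces the row's stored `β` interval to printed rounding. It does not
establish anything about real fish beyond what those published ranges
already claim, and the model itself omits every sensory pathway except the
lateral line, so quantitative comparison with behaving animals is outside
what any test here can license.

## Known limitations

* Planar, inviscid, far-field: no wakes, no boundary layers, no
  three-dimensional effects, no near-field hydrodynamics within `~r0`.
* Inertialess swimmer: transient and unsteady effects (added mass,
  elasticity) are absent.
* The feedback is a single linear gain on circulation; saturations or
  frequency dependence of the lateral line are not modelled. (Linear
  stability at the centerline would be unchanged by smooth nonlinear
  feedback laws, but trajectories away from it would not.)
* Wall contact, and therefore any stick-slip component of real sweeping, is
  excluded by construction.
* The A-dipole turning rule (fiducial points along the direction of motion)
  is not implemented; the package commits to the transverse (T-dipole) rule.
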