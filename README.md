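# rheodipole

Why can fish hold station against a current — rheotaxis — even in the dark,
and why do they then sweep periodically from side to side across the channel?
`rheodipole` implements a minimal, bidirectionally coupled fish–fluid model
that answers both questions with a two-dimensional potential-flow calculation
and a planar dynamical system. It is aimed at researchers in fish
biomechanics, sensory ecology and minimal models of locomotion who want a
reproducible, testable implementation of the channel–dipole picture:
the swimmer is not a passive tracer of the background flow but an *invasive
sensor* whose own flow field reflects off the walls and pushes back on it.

## The model

A fish of speed `v0` is a finite vortex dipole of length scale `r0` (on the
order of the tail-beat amplitude) in an infinite channel of width `h`, walls
at `y = 0` and `y = h`. The dipole potential at `r` for a swimmer at `r_f`
with heading `θ_f` is

```
φ_f(r) = − r0² ((r − r_f) · v_f) / ‖r − r_f‖²,   v_f = v0 (cos θ_f, sin θ_f).
```

No-penetration at both walls is enforced by an infinite lattice of image
dipoles (four per reflection level); the package evaluates the image series
with an analytic Euler–Maclaurin tail correction and cross-checks it against
an independently derived cotangent-lattice closed form. A weakly rotational
background profile

```
u_b(y) = U0 (1 − 4ε (y/h − 1/2)²) x̂
```

carries the swimmer and contributes the only vorticity in the channel,
`ω = (8 U0 ε / h)(y/h − 1/2)`. The lateral line senses the circulation over
a body-sized rectangle and feeds it back linearly into the turn rate with
gain `K`.

Nondimensionalizing (`ξ = y_f/h − 1/2`, time in units of `h/v0`) collapses
everything onto three groups — `ρ = r0/h`, `α = U0 ε / v0`, `κ = K r0 l` —
and the planar system

```
ξ̇  = [1 − (π²ρ²/12)(3 csc²(π(ξ+½)) − 1)] sin θ_f
θ̇_f = −(π³ρ²/4) cot(π(ξ+½)) csc²(π(ξ+½)) cos θ_f + 8 α ξ (cos²θ_f + κ).
```

Upstream swimming (`θ_f = π`, `ξ = 0`) is stable — a neutral center ringed by
periodic cross-stream sweeping orbits of small-amplitude frequency
`ω₀ = √(det A) ≈ (π²/2) ρ √(β/β* − 1)` — if and only if the single
bifurcation parameter `β = α(1+κ)/ρ²` exceeds `β* = π⁴/32 ≈ 3.044`. Below
threshold the fish cannot hold an upstream heading; above it, two additional
off-center upstream equilibria appear (always saddles) in a pitchfork-like
bifurcation.

## Worked example

```r
library(rheodipole)

p <- nondim_params(rho = 0.1, alpha = 0.1, kappa = 1)   # beta = 20
find_equilibria(p)
#> Planar-system equilibria (beta = 20, beta* = 3.04403):
#> <equilibrium> theta = 0, xi = 0: saddle (det A = -1.8132)
#> <equilibrium> theta = pi, xi = 0: neutral_center (det A = 1.33416)
#> <equilibrium> theta = pi, xi = 0.332874469: saddle (det A = -7.31167)
#> <equilibrium> theta = pi, xi = -0.332874469: saddle (det A = -7.31167)

sweeping_frequency(p)            # exact: sqrt(det A) at (pi, 0)
#> [1] 1.15506
sweeping_frequency(p, "small_rho")
#> [1] 1.164679
```

With `β = 20 > β*`, downstream swimming is a saddle (any perturbation grows),
upstream swimming at the centerline is a neutral center (stable rheotaxis),
and the two equilibria at `ξ = ±0.333` are the unstable near-wall branches of
the pitchfork. The sweeping frequency `ω₀ ≈ 1.155` radians per `h/v0` means a
fish crossing the channel in, say, 5 s sweeps at about 0.23 rad/s. A
trajectory launched slightly off-center stays bounded and oscillates:

```r
tr <- simulate_planar(c(0.05, pi), p, 60)
attr(tr, "termination"); max(abs(tr$xi))
#> [1] "horizon"
#> [1] 0.05
```

Literature-derived parameter ranges ship as presets, and the feedback gain
can be estimated from rheotaxis threshold speeds with and without the
lateral line (`U_c` ratio minus one):

```r
preset_nondim("mexican_tetra")
#> <nondim_params> rho = 0.066, alpha = 0.12, kappa = 0, beta = 27.5482 (beta* = 3.04403)
kappa_from_thresholds(Uc_ablated = 6, Uc_intact = 2)
#> [1] 2
```

## Command line

All analyses are scriptable via `rheo_cli()` or the shipped launcher:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "rheodipole.R", package = "rheodipole"))')
Rscript "$CLI" analyze  --rho 0.1 --alpha 0.1 --kappa 1 --out out/   # stability report (JSON)
Rscript "$CLI" field    --h 1 --U0 0.5 --eps 0.2 --v0 1 --r0 0.05 --out out/  # flow-field CSV
Rscript "$CLI" sweep    --rho 0.05 --alpha 0.01 --out out/           # bifurcation diagram CSV
Rscript "$CLI" simulate --rho 0.1 --alpha 0.1 --kappa 1 --xi 0.05 --out out/  # trajectory CSV
Rscript "$CLI" fig5     --out out/                                   # transcendental curves CSV
```

Flags can come from a flat JSON file (`--config`), `--preset <label>` loads a
packaged literature preset, and every output embeds the resolved parameters
and package version.

## Scope

The model is inviscid and planar: no boundary layers, wakes or Navier–Stokes
solving; no wall contact or impact (integration stops at a wall-proximity
band); background turbulence enters only through the time-averaged shear
parameter `ε`. See `vignettes/rheotaxis-dipole-model.Rmd` for the full
account of assumptions, numerical choices and limitations.
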