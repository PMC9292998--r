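Package: rheodipole
Title: Vortex-Dipole Model of Fish Rheotaxis in a Channel Flow
Version: 0.1.0
Authors@R:
    person("Dynamical", "Modeller", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bidirectionally coupled fish-fluid model of rheotaxis: a finite
    vortex dipole swimming in an infinite two-dimensional channel with a
    weakly rotational background flow. Implements the potential flow of the
    dipole and its wall images (truncated image series with analytic tail
    correction, plus an independently derived closed form), the de-singularized
    advective velocity and hydrodynamic turn rate, circulation-based lateral
    line feedback, trajectory simulation with wall-proximity events, and the
    reduced nondimensional planar dynamical system: equilibria of the
    transcendental equation, zero-trace linearization, saddle/neutral-center
    classification, the pitchfork-like bifurcation at beta* = pi^4/32, and the
    cross-stream sweeping oscillation frequency. Ships literature-derived
    parameter presets and a command-line interface for field evaluation,
    stability reports, bifurcation sweeps, and trajectory export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
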