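Package: colloco
Title: Direct Collocation Optimal Control for Muscle-Driven Multibody Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for predicting, tracking, and inversely
    solving motions of small muscle-driven multibody models with direct
    collocation. Provides planar rigid-body models (pin/slider chains, point
    masses) actuated by smooth Hill-type muscles with activation dynamics and
    rigid or compliant tendons, torsional springs, smooth sphere-plane
    contact, and holonomic kinematic constraints handled with Lagrange
    multipliers. Continuous optimal-control problems (effort, tracking,
    final-time and joint-reaction goals; boundary and path constraints; free
    model parameters) are transcribed with trapezoidal or Hermite-Simpson
    schemes, with explicit or implicit multibody dynamics, and solved by a
    sparse augmented-Lagrangian nonlinear-program solver. Includes tools for
    the muscle-redundancy (inverse) problem and motion tracking, STO-style
    time-series input/output, and a runnable verification suite (analytic
    steering benchmark, prediction/time-stepping consistency, tracking
    recovery, mesh-convergence analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
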