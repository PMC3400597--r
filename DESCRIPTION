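Package: dnifield
Title: Closed-Loop Simulation of a Dynamic Bidirectional Neural Interface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a dynamic bidirectional neural interface that shapes a
    desired force field around a simulated point mass. A sensory map encodes
    the position of the mass into one of a small vocabulary of stimulation
    patterns, and a motor map decodes the evoked spike-count population
    response into a planar force, so that the closed loop approximates a
    linear convergent force field and drives the mass to its equilibrium.
    Includes the concurrent calibration ("dynamic shaping") of both maps from
    repeated stimulus-conditioned responses, exact zero-order-hold point-mass
    dynamics in a viscous medium, a stimulus-conditioned spike-count generator
    with a configurable variance-mean power law, trajectory quality metrics,
    and mutual-information evaluation with limited-sampling bias correction
    (analytic, shuffle and bootstrap cascade) plus parameter sweeps over
    binning and population size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    MASS,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
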