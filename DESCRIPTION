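Package: vstorage
Title: Three-Dimensional Velocity Storage Modelling of Vestibular
    Gravitational Pull
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the central vestibular velocity storage integrator as a
    three-dimensional linear dynamical system with roll, pitch and yaw
    components.  Builds normal (diagonal) and cross-coupled ("gravitational
    pull") system matrices, computes the eigenvector that represents the
    internal estimate of the up direction and its misalignment with the head
    vertical, and evaluates the closed-form zero-input response that
    corresponds to idealized optokinetic after-nystagmus (OKAN).  A scenario
    engine applies velocity storage attenuation interventions (yaw
    time-constant reduction, yaw output-gain reduction, optokinetic
    coupling reduction) and reports how each changes the misalignment angle.
    A trace generator produces figure-style sampled slow-phase velocity
    traces with injected noise, and a least-squares fitting layer recovers
    model parameters from such traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
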