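Package: vjump
Title: Generalised Velocity-Jump Processes with Resting States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the two-state generalised velocity-jump process, a
    non-Markovian correlated random walk in which straight runs at constant
    velocity alternate with stationary rests of arbitrarily distributed
    duration. Provides run/rest duration laws (exponential, gamma, inverse
    Gaussian) with analytic Laplace transforms, renewal-type delay kernels
    with numerical Talbot and Euler Laplace inversion, a Gillespie sample-path
    simulator with von Mises reorientation, a trapezoidal/Crank-Nicolson
    solver for the closed system of mean-squared-displacement moment
    equations together with an independent Laplace-space solver, the
    closed-form large-time effective diffusion constant, and parameter
    extraction from movement tracks: run/rest segmentation of coarse GPS
    records by windowed convex-hull diameter thresholding, maximum-likelihood
    fitting of duration and turning-angle distributions, and synthetic track
    generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    geosphere,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
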