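Package: motrack
Title: Motion-Type Classification of Single-Particle mRNA Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing live-imaging trajectories of single mRNA
    particles in neurites. Computes time-averaged mean squared displacement
    (MSD) curves, fits the anomalous diffusion model MSD = A*tau^alpha + B by
    bounded nonlinear least squares, and classifies each track as actively
    driven, diffusive or confined from the fitted exponent. Net and lateral
    maximal displacement along the neurite axis classify tracks as directed,
    stationary or oscillatory. A trajectory simulator with ballistic, Brownian
    and confined (reflecting corral) motion modes and Gaussian localization
    noise provides ground truth; a pipeline aggregates class fractions per
    culture replicate and compares genotype groups with Welch's t test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
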