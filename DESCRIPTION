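Package: induceR
Title: Inference of Network Directionality Using Covariance Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Causal-direction inference for pairs of biomolecular species from
    single-cell snapshot data (INDUCE). Models fluctuations of log
    concentrations around steady state as a stationary multivariate Langevin
    (Ornstein-Uhlenbeck) process, links network connectivity and noise to the
    stationary covariance matrix through the Lyapunov equation, and exploits
    the predictable co-movement of covariance-matrix elements as a connection
    strength is swept by a dose-response perturbation. Includes analytic and
    numeric covariance trajectories for small network motifs parameterized by
    Hill transfer functions, a synthetic single-cell data generator with
    lognormal marginals (plus an Euler-Maruyama simulator for
    cross-validation), the two-node variance-versus-covariance model fit with
    bootstrap uncertainties, and an exact paired Wilcoxon signed-rank test
    comparing the two directed models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    Matrix,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
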