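Package: condgauss
Title: Conditional Gaussian Multiscale Nonlinear Stochastic Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for conditionally Gaussian multiscale nonlinear
    stochastic systems: exact closed-form nonlinear filtering of the hidden
    subspace given an observed path, an efficient Fokker-Planck solver built
    from conditional Gaussian mixtures with block decomposition and
    statistical symmetry, filter-based parameter-estimation schemes,
    information-theoretic model-error metrics, and a conditional-Gaussian
    mixture particle-filter analysis step.  Ships a registry of stochastic
    test models from biology and geophysics (FitzHugh-Nagumo lattices, SIR,
    predator-prey, tumour-nutrient, Lorenz-type and triad/dyad turbulence
    models) together with an Euler-Maruyama simulator used as the synthetic
    data source.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
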