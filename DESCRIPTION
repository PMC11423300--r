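Package: saxsdlvo
Title: Colloidal Interaction Parameters from Small-Angle Scattering via
    Monte Carlo Simulation, Neural Surrogates and MCMC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts effective macroion valency and Debye length from
    small-angle X-ray scattering (SAXS) curves of charged colloidal
    suspensions. A Metropolis Monte Carlo engine samples configurations of
    DLVO spheres (Hamaker van der Waals attraction plus screened-Coulomb
    repulsion) in a periodic box, radial distribution functions are
    transformed into structure factors and composed with the sphere form
    factor into labelled synthetic SAXS curves. A dense forward neural
    network predicts the interaction parameters from a curve, and an
    inverse network serves as a fast surrogate simulator inside an
    affine-invariant ensemble Markov chain Monte Carlo sampler that returns
    maximum a posteriori estimates, credible intervals and parameter
    correlations for a measured curve.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
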