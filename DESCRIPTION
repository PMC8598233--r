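Package: focisim
Title: Stochastic Models and Single-Particle-Tracking Observables for
    Membrane-Less Nuclear Foci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators and analysis tools for two physical models of
    membrane-less nuclear foci (condensates): the Liquid Phase Model, in
    which a tracer diffuses in a droplet described by sigmoidal potential
    and diffusivity profiles, and the Polymer Bridging Model, in which the
    focus is a dense cluster of diffusing, partially absorbing binding
    sites that transiently trap the tracer. Includes overdamped Langevin
    integration with position-dependent diffusivity (Milstein scheme), an
    event-resolved binding-site simulator with Robin-type partial
    absorption, the mean-field effective description connecting the two
    models, single-particle-tracking observables (displacement histograms,
    radial diffusivity/density profiles, mean radial displacement, angle
    distributions) used to discriminate the models, and first-passage-time
    and concentration-sensing theory for a target inside a focus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
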