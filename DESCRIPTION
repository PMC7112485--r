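Package: epimux
Title: Coupled Awareness-Epidemic Dynamics on Time-Varying Multiplex Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models the interplay between epidemic spreading and the diffusion
    of awareness about the epidemic on a two-layer multiplex network. The
    awareness layer is a time-varying contact network generated by the
    activity-driven model; the contagion layer is a static scale-free network
    on the same nodes. Provides the microscopic Markov chain approach (MMCA)
    for the coupled unaware/aware susceptible-infected-susceptible dynamics,
    the linearized spectral computation of the epidemic threshold
    (beta_c = mu / Lambda_max of the awareness-modulated adjacency), stochastic
    Monte Carlo simulation with parallel updating, and experiment drivers for
    phase diagrams, model comparisons, fluctuation-ratio analysis and
    threshold-difference maps. Awareness can spread as a
    susceptible-infected-susceptible process or as a linear-threshold
    (Watts-type) cascade.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
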