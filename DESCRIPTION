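Package: asymcoal
Title: Genealogies of Populations with Non-Heritable Asymmetric Reproductive Success
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Forward simulation and coalescent-limit analysis for neutral
    discrete-time populations in which reproductive success is asymmetric but
    not heritable (asymmetric Cannings and asymmetric Wright-Fisher models).
    Provides canonical set partitions with the coagulation operator and
    paint-box sampling, exact Xi- and Lambda-coalescent collision rates with a
    continuous-time reference simulator, exact and Monte-Carlo one-generation
    transition matrices, convergence diagnostics (size-biased moment
    functionals, Lambda- and Kingman-criteria), and a model zoo: generalized
    Eldon-Wakeley reproduction, recurrent bottlenecks, Poisson-Dirichlet
    power-law family frequencies, and an exponential branching-selection
    particle system whose genealogy reduces to the Poisson-Dirichlet case.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
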