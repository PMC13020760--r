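Package: episcape
Title: Functional Bottlenecks in Global-Epistasis Fitness Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of stylized fitness landscapes with
    global (but no network) epistasis. An additive underlying trait built
    from random single-mutation effects is mapped to two mutually exclusive
    phenotypes through nonlinear fitness functions; two reference variants
    are constructed by a stochastic greedy/random tuning procedure, and the
    space of directed mutational paths between them is analyzed for
    functional bottlenecks via a maximin (widest-path) connectivity
    threshold. Includes the calibration pipeline that sets the tuning
    parameters, ensemble drivers for landscape-topology statistics, and an
    analyzer for measured two-phenotype combinatorial landscapes
    (normalization, trait deconvolution, single-mutation-effect spectra,
    Pareto tail fits, bottleneck topology) together with a synthetic
    fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
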