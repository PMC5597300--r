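Package: fracdomain
Title: Fractal Chromatin Domains from Subdiffusive Nucleosome Movement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links the subdiffusive movement of single nucleosomes to the
    organization of chromatin domains through polymer physics. Generates
    polymer chain conformations with prescribed fractal dimension (straight
    line, ideal random walk, excluded-volume self-avoiding walk, space-filling
    globule, and fractional-Brownian chains), estimates fractal dimensions
    from the internal-distance scaling law, provides a generalized Rouse
    forward model with fractional (viscoelastic) thermal noise whose monomer
    mean-squared displacement follows MSD(t) = D_sub t^beta with
    beta = 2*alpha/(2 + d_f), simulates single-monomer trajectories by exact
    circulant-embedding sampling, fits subdiffusion parameters from
    single-particle-tracking ensembles, and inverts the mobility-structure
    relations to recover the fractal dimension and relative size of the
    underlying domain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
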