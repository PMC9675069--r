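Package: mixoevolve
Title: Eco-Evolutionary Dynamics of Temperature-Dependent Mixotrophy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adaptive-dynamics analysis of a mixotrophic plankton model in
    which single-celled algae combine depth-integrated photosynthesis with
    phagotrophic grazing on logistically growing bacterial prey, and both
    metabolic rates scale with temperature. Provides the population-dynamic
    rate functions, resident equilibrium solvers with viability and local
    stability reporting, invasion fitness and selection gradients, pairwise
    invasibility plots, detection and classification of evolutionarily
    singular strategies (ESS, branching point, repeller, neutral),
    trait-substitution continuation of the evolutionarily stable
    phagotrophic investment across temperature, light and prey-availability
    landscapes, and evolving-versus-static comparisons of equilibrium
    carbon-fixation and remineralization proxies. Includes a command-line
    interface and YAML scenario configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
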