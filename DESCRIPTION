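Package: phycogradients
Title: Nutrient Gradients Around Algal Cells and Across Porous Co-Culture Microplates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-scale models of the nutrient landscape that algal-associated
    bacteria experience: steady-state radial diffusion of dissolved organic
    carbon (DOC, exuded at the cell surface) and nitrate (taken up at the cell
    surface) around a single phytoplankton cell (the phycosphere), and a
    compartment ODE model of DOC and nitrate dynamics in a graph of culture
    wells coupled by diffusion through porous copolymer walls and an external
    medium reservoir. Includes a synthetic algal-bacterial co-culture
    generator (Monod growth of exudate-specialist and generalist taxa on the
    simulated nutrient fields, flow-cytometry-like count sampling, 16S-like
    relative-abundance tables) and the spatial statistics used to quantify
    distance responses: specific growth rates, geometric summaries, distance
    fold-changes, Welch t-tests, balanced two-way ANOVA interaction tests and
    permutation trend tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'units.R'
    'AllClasses.R'
    'AllGenerics.R'
    'phycosphere.R'
    'microplate.R'
    'community.R'
    'cytometry.R'
    'spatial-stats.R'
    'config.R'
    'experiments.R'
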