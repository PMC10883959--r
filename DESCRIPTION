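Package: invasim
Title: Establishment and Impact of an Exotic Generalist Predator in a
    Native Predator-Prey System
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing a three-species Lotka-Volterra invasion
    model in which an exotic generalist predator both consumes a native
    prey and competes with a native specialist predator.  Provides
    closed-form equilibria and analytic stability conditions for the
    two-species native system and the three-species invaded system,
    numerical eigenvalue classification, stiff-capable trajectory
    simulation, classification of long-run outcomes into establishment
    scenarios, two-parameter (predation/competition ratio) scenario
    maps, minimum-propagule-size estimation under bistability, and
    trophic-impact ratios of exotic presence on native densities.
    Includes canonical parameter fixtures (a theoretical set and an
    American mink set) and seeded sampling of the documented parameter
    ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
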