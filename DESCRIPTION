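Package: coopcell
Title: Social Fitness Statistics and Evolutionary-Game Models of Altruistic
    Cancer-Cell Cooperation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying altruistic cooperation among cancer cells
    in co-culture and simulation. Implements the social-fitness statistics used
    in tagged co-culture competition assays (relative survival, relative
    fitness, the Hamilton-style social-behaviour matrix, percentage and
    marginal benefit with linear-versus-quadratic shape selection, rescue and
    percentage-effect formulas), a well-mixed evolutionary public-goods game
    with a saturating (concave) diffusible benefit and replicator dynamics, a
    lattice agent-based tumor model contrasting genetic with epigenetic
    inheritance of the altruistic fate, a secrete-and-sense lateral-inhibition
    patterning model, and a seeded synthetic-data generator emulating the
    tagged co-culture, dose-titration and fluorescence-sorting experimental
    designs so that every analysis stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
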