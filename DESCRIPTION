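Package: wallfem
Title: Finite-Element Simulation of Abdominal-Wall Mechanics with Stoma
    Incisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear-elastic finite-element analysis of the human abdominal
    wall under intraabdominal pressure, aimed at stoma (ostomy) placement
    studies. Provides a tagged tetrahedral mesh model with Gmsh and VTK
    interchange, a deterministic generator of a curved multi-layer
    abdominal-wall phantom with an optional circular trephine incision at
    labelled grid positions, a P1 tetrahedral elasticity solver with
    surface-pressure loading and von Mises stress post-processing, and
    trephine-enlargement morphometry (deformed perimeter, area, diameters
    and percent increases). A configuration-driven runner sweeps stoma
    positions and pressure levels and reports tidy result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
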