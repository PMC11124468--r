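Package: pedspine
Title: Parametric Solid 3D Models of the Pediatric Lumbar Spine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates solid-state, tissue-labelled 3D models of pediatric
    lumbar vertebrae, intervertebral discs and assembled lumbar spines for
    five age groups (newborn through preadolescent), from packaged
    osteometric mean dimensions and a biomechanical material registry.
    Includes a triangle-mesh solid-geometry kernel (revolve/extrude/box
    primitives, field-based boolean operations, edge rounding, watertight
    measurement), a 12-step parametric vertebra builder with age-dependent
    component architecture (bone and cartilage), a wedge-shaped disc builder
    with nucleus cavity, a lordosis-aware spine assembler, a morphometric
    validation suite that re-measures generated solids against the packaged
    dimension table, and STL/OBJ/PLY export with a material manifest for
    finite-element preprocessing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    jsonlite,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
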