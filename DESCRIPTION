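Package: chipflow
Title: Fast Simulation of Fluids and Particles in Microfluidic Chips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates pressure-driven flow and particle transport in
    lab-on-chip microfluidic devices built from rectangular channels and
    T- or cross-shaped intersections. Channel networks are solved through
    the electrical-circuit analogy (hydraulic resistance, Kirchhoff's
    laws); intersections are solved once as two-dimensional incompressible
    Stokes flow on a staggered grid, stored in a reusable library, and
    retrieved by nearest-match queries; whole-chip particle paths are then
    stitched from per-intersection trajectories using the streamline
    (cumulative flow fraction) coordinate. Includes generators for
    reference chip layouts, a direct whole-chip solver used as an internal
    oracle, and plotting and tidying methods for all result types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
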