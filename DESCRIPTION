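Package: semiflex
Title: Statistical Mechanics of Semiflexible Filaments at Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form statistics and seeded Monte-Carlo samplers for
    worm-like chains (WLC) and augmented filament models in two dimensions:
    tangent correlations and chain dimensions of the 2D/3D WLC; loop/tail
    statistical weights, proximal and layered concentration profiles,
    chemisorption length scales and a kinetic Monte-Carlo model of
    irreversible zipping at a flat wall; the ground-state mechanics of a
    helical filament squeezed onto a plane (twist-kinks, Jacobi elliptic
    profiles, shape reconstruction); the exact deflection-angle statistics
    of the arc/arc twist-kink gas; shear-coupled bundle screening and
    tail-induced bistability; and the polymorphic lattice model of
    microtubule curvature with its force-torque phase diagram. Every closed
    form ships with an independent numerical or Monte-Carlo oracle used in
    the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
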