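Package: arftrace
Title: Finite-Size Acoustic Radiation Forces and Acoustophoretic Particle Tracing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the acoustic radiation force (ARF) on bio-particles in
    standing ultrasound fields, both under the classical small-particle (Gorkov)
    assumption and with a finite-particle-size correction obtained by volume
    averaging the small-particle force over the particle. Includes the
    closed-form one-dimensional modifying factor and its zero crossing, material
    property registries with derived-quantity formulas and validity diagnostics,
    multi-directional standing-wave fields and force maps, and quasi-static
    Stokes-drag particle tracing for microfluidic separation and patterning
    scenarios. All results are returned as tibbles with ggplot2 plotting
    helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite,
    deSolve,
    pracma,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
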