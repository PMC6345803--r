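Package: septcurve
Title: Curvature-Sensing Adsorption of Septin Filaments on Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Free-energy model of septin filament and bundle adsorption on
    curved membranes: optimal, threshold and maximum adsorption curvatures,
    bundle scaling laws, orientation regimes on wavy substrates, and the
    parallel-versus-circumferential theory of septin rearrangement at the
    yeast bud neck during cytokinesis. Also provides the companion
    measurement procedures as reusable estimators (worm-like-chain
    persistence length from tangent correlations, dissociation constant from
    Hill binding isotherms, bending and stretching moduli from micropipette
    aspiration, and spike geometry from vesicle contours), together with
    seeded synthetic-data generators for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
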