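Package: tactoidMC
Title: Hard-Rod Monte Carlo and Director-Field Analysis in Tactoid-Shaped Confinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation of hard spherocylinders confined to shallow
    spindle-shaped (tactoid-mimicking) quasi-2D containers, together with the
    analysis stack needed to characterise the resulting colloidal liquid-crystal
    textures: global and local (length-weighted) nematic tensor order parameters,
    angular-deficit maps, winding-number detection of half-integer disclinations,
    classification of director-field patterns (homogeneous, bipolar, diagonal,
    wavy and multi-domain states), and classification of the melt/slide/turn
    equilibration pathways from controlled initial states. Includes analytic
    director-field generators for every pattern class so the analysis stack can
    be validated without running simulations, an extended-XYZ trajectory format,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
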