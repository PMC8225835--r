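Package: epidermsim
Title: Agent-Based Simulation of Epidermal Homeostasis on a Deformable Dermis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three-dimensional off-lattice cell-center model of the epidermis
    coupled to a deformable dermis. The dermis is a slab of mutually adhesive
    particles, the basement membrane an elastic triangulated sheet with
    stretching and bending energies, and keratinocytes are spheroids that
    divide in the basal layer, delaminate, differentiate under calcium and a
    second cornification-derived stimulant, flatten, produce and release
    lipids, and desquamate under corneodesmosome decay. Includes layer-quality
    morphometrics (thickness, vertical dispersion, spatial variation on a
    subregion grid), scenario presets for homeostasis, reduced cell supply,
    dermal stiffening and corn (clavus) formation, and a desquamation
    calibration routine anchored to a 14-day cornification-to-shedding lag
    and a 28-day epidermal turnover.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
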