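Package: marginflow
Title: Self-Organized Margin Mechanics and Epiblast Flows in Early Avian Development
Version: 0.1.0
Authors@R:
    person("Margin", "Flow Developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mechanical models of embryonic regulation in the early avian
    (quail) epiblast. Implements a one-dimensional activator-inhibitor model
    of self-organized actomyosin contractility on the embryo margin, where
    contractility self-activates locally and passive tension acts as a fast,
    long-range inhibitor; a two-dimensional fluid-mechanical model of
    epiblast tissue flows driven by a viscoelastic margin line with a
    saturating walking kernel, substrate friction and prescribed areal
    growth (epiboly, primitive-streak ingression); perturbation scenarios
    (bisection, free versus attached boundaries, localized friction
    obstacles, contractility drugs); and the quantification pipeline used to
    analyse tracked tissue motion: strain-rate kymographs, contracting-domain
    size, integrated contraction, deformation maps, expression-domain
    statistics and permutation tests. Includes seeded synthetic-data
    generators emulating particle-image-velocimetry margin tracking and
    expression imaging so that the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
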