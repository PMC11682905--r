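Package: chipgraft
Title: Clonal Hematopoiesis Dynamics After Allogeneic Stem Cell
    Transplantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic compartmental modeling of neutrophil
    reconstitution and donor-derived CHIP (clonal hematopoiesis of
    indeterminate potential) clone dynamics after allogeneic
    hematopoietic stem cell transplantation.  Implements a
    feedback-regulated multi-compartment ODE model of the neutrophil
    lineage (stem cells, progenitor stages, circulating neutrophils)
    with Hill-type systemic and niche feedback, a multi-clone extension
    with mutant parameter modifications and aberrant signal
    sensitivity, quasi-steady-state coupling of CHIP-driven systemic
    inflammation, a pegfilgrastim-like pharmacokinetic submodel, graft
    construction and homing, and a virtual-clinical-trial engine for
    dose, graft-composition and donor-recipient correlation
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
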