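Package: cableRT
Title: Reciprocity-Based Prediction of Neural Responses to Electric Brain
    Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts subthreshold membrane-potential responses of passive
    multicompartment neuron models to extracellular (ES) and transcranial
    (tES) electric stimulation by exploiting the reciprocity theorem: one
    frequency-domain cable solve for an intracellular current injection
    yields, through the extracellular potential it generates, the membrane
    response to stimulation from any extracellular site. Includes an SWC
    morphology reader and synthetic morphology builders (ball-and-stick,
    myelinated axon), a passive compartmental cable solver in the frequency
    domain, point-source/monopole/dipole forward models of the extracellular
    potential, closed-form ball-and-stick transfer functions for the somatic
    membrane current and the current-dipole moment, a traditional
    extracellular-boundary-condition solver for validation, an ES-proxy
    equivalent-current calculator, and a head-model layer (four-sphere model
    and lead-field matrices) for transcranial stimulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
Collate:
    'units.R'
    'AllClasses.R'
    'morphology.R'
    'swc.R'
    'cable.R'
    'spectrum.R'
    'fields.R'
    'reciprocity.R'
    'analytic.R'
    'foursphere.R'
    'leadfield.R'
    'tes.R'
    'stimulus.R'
    'fixtures.R'
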