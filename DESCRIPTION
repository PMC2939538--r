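Package: osmoreg
Title: Discrete-Time Simulation of Rat Hydromineral Homeostasis and
    Vasopressin Feedback
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A minute-resolution feedback simulator of whole-body water and
    sodium balance in the laboratory rat. The model tracks extracellular
    sodium concentration, intra- and extracellular fluid volumes, plasma
    vasopressin (AVP), urine output and drinking behaviour, coupling an
    osmotically driven two-compartment body-fluid model to an AVP
    controller with clearance-limited decay and circadian modulation, a
    kidney with aldosterone and atrial-natriuretic-peptide volume feedback,
    a stomach/intestine transit model and a stochastic drinking-motivation
    module. Built-in protocols reproduce hypertonic saline infusion
    (intracellular dehydration), furosemide plus sodium-deficient diet
    (extracellular dehydration), forced-drinking and blocked
    intracellular-exchange virtual experiments, with circadian averaging,
    restoration/maintenance phase detection and daily summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
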