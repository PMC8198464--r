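Package: langmuirkit
Title: Analysis of Langmuir Monolayer Experiments on Model Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of Langmuir trough experiments on
    phospholipid monolayers used as model cell membranes, with an emphasis
    on nanoparticle-lipid interaction studies. Covers pi-A isotherm
    thermodynamics (compression modulus, Davies-Rideal phase
    classification, liquid-expanded/liquid-condensed transition
    parameters, extrapolated areas and isotherm shifts), dilatational
    viscoelasticity from oscillating-barrier traces by fixed-frequency
    harmonic regression, monolayer penetration kinetics from paired
    penetration/reference traces, and Owens-Wendt two-liquid surface free
    energy from contact angles. A synthetic-data generator emulates the
    instrument outputs with known ground-truth parameters so that every
    analysis stage can be validated closed-loop without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
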