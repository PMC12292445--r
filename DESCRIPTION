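Package: bariPBPK
Title: Physiologically Based Pharmacokinetic Simulation of Oral Drug
    Absorption After Bariatric Surgery
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic simulation of oral drug dissolution, gastrointestinal
    transit and absorption coupled to linear three-compartment systemic
    disposition, with gut-physiology scenarios for bariatric surgery (sleeve
    gastrectomy and one-anastomosis gastric bypass). Implements a capped
    Henderson-Hasselbalch pH-solubility model for multiprotic drugs with
    bile-salt solubilization, Johnson-type particle dissolution and
    precipitation kinetics, an in vitro paddle-vessel dissolution simulator
    with hydrodynamic paddle-speed scaling, a nine-compartment
    compartmental-absorption-and-transit gut model with surgery-specific
    rewiring, compartmental parameter fitting and non-compartmental analysis,
    and the fold-error/R-squared model-validation arithmetic. Ships a
    vardenafil parameter set as the worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
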