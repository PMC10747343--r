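Package: tenapbbm
Title: Physiologically Based Biopharmaceutics Model of Sodium-Tenapanor
    Interaction in the Human Gut
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mechanistic gastrointestinal simulation of dietary sodium
    handling under tenapanor, a minimally absorbed NHE3 (sodium/hydrogen
    exchanger isoform 3) inhibitor used in irritable bowel syndrome with
    constipation.  A nine-segment compartmental absorption and transit
    model couples luminal sodium, diffusion-layer tenapanor dissolution
    with salt-limited solubility and precipitation, saturable NHE3 sodium
    uptake with competitive inhibition and meal(sodium)-stimulated Hill
    induction, and systemic disposition, to predict daily urine and stool
    sodium excretion under arbitrary dosing and meal schedules.  Includes
    built-in replicas of three clinical study designs, placebo calibration
    of the transporter capacity and renal clearance, a synthetic
    observed-data generator, and prediction-accuracy statistics (AAFE,
    AFE, fold-error envelopes, stool-versus-urine change correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
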