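Package: reperfusim
Title: Charge-Difference Cardiomyocyte Simulation of Ischemia and Reperfusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic single-cell simulator of myocardial ischemia and
    reperfusion in the guinea-pig ventricular myocyte. The model couples a
    charge-difference (concentration-based) membrane potential to Luo-Rudy
    dynamic membrane currents, dynamic intra- and extracellular pH with
    bicarbonate and intrinsic buffering, acid transporters (NHE, NBC, CHE, AE)
    with allosteric proton regulation of the sodium-proton exchanger,
    ATP/phosphometabolite schedules, osmotic water flux with dynamic
    compartment volumes, and an isolated extracellular space during ischemia.
    Includes the three-phase ischemia-reperfusion protocol engine with
    NHE-inhibition and sodium-potassium-pump intervention scenarios, per-beat
    metrics, and per-pathway sodium flux accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
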