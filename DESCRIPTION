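Package: fibercapture
Title: Growth Factor Capture by Endothelial-Lined Hollow Fibers Under Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates single-pass capture of a heparin-binding growth factor
    (FGF-2) by endothelial cells lining the hollow fibers of a perfusion
    bioreactor. Couples pulsatile laminar tube flow and axisymmetric
    convection-diffusion of the fluid-phase ligand to a cell-surface
    mass-action network of FGF receptor (FGFR) and heparan sulfate
    proteoglycan (HSPG) binding, receptor-proteoglycan coupling,
    dimerization, and internalization, imposed as a wall boundary condition.
    Includes the inlet-reservoir dilution model, outflow fraction
    accounting, mass ledgers, simulation/experiment agreement criteria,
    ready-made scenario presets, and a synthetic outflow-curve generator
    for testing the analysis tools.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    rlang,
    tibble,
    tidyr,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
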