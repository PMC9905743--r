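Package: drnvta
Title: Mean-Field Simulation and Degeneracy Screening of DRN-VTA Neuromodulator Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating mean-field firing-rate models of the dorsal raphe
    nucleus (DRN) and ventral tegmental area (VTA) neuromodulator circuit: five
    interacting neural populations (serotonin, dopamine, glutamate, and two GABA
    pools) coupled through fast synaptic currents and slow sigmoidal
    neuromodulator-induced currents, with Michaelis-Menten release-and-reuptake
    dynamics for serotonin and dopamine. Provides reward and punishment task
    protocols for Type I and Type II serotonin neurons, a registry enumerating 84
    degenerate circuit variants over twelve architectures, fixed-point and Jacobian
    eigenvalue stability analysis, an inclusion-criterion degeneracy screen against
    a calibrated template activity profile, and a simulated D2-receptor agonist
    perturbation screen that scales dopamine-sourced connection weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    lhs,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
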