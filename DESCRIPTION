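Package: qtrap
Title: Nonequilibrium Work and Alchemical Free-Energy Analysis for
    Quinone Channel Trapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-simulation inference tools for molecular-dynamics studies
    of substrate trapping in the ubiquinone (CoQ10) channel of respiratory
    complex I.  Turns ensembles of steered-MD pulling work traces into
    binned work profiles and Jarzynski free-energy estimates, estimates
    alchemical free-energy differences per lambda window with Bennett's
    acceptance ratio and composes them into a thermodynamic-cycle relative
    binding free energy with k-nearest-neighbor endpoint density
    corrections, converts barrier-height differences into Boltzmann rate
    slowdown factors, and analyses donor-acceptor distance distributions
    for density modes and nonadiabatic (Marcus) electron-tunneling rate
    ratios.  Includes a synthetic-data module (overdamped Langevin pulling
    on model potentials, Crooks-consistent alchemical samples, Gaussian
    distance mixtures) so every estimator has a ground-truth recovery test,
    plus readers for plain TSV tables and MD-engine SMD-log and fepout
    dialects.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
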