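Package: looplab
Title: Loop-Closure Kinetics of Unfolded Peptide Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for end-to-end loop-closure kinetics in
    unfolded polypeptide chains probed by contact-quenching fluorescence
    signals. Provides fluorescence-state assignment from end-to-end minimum
    distances, second-order fluorescence autocorrelation and hydrogen-bond
    existence autocorrelation, two-state and multi-exponential kinetic
    fitting with closing/opening time-constant conversion, power-law
    scaling of closure rates with chain length, probability-density-based
    free-energy profiles with automatic open/closed cutoff selection, and
    backbone hydrogen-bond and beta-segment analysis (geometric and
    Kabsch-Sander criteria). Synthetic-data generators (telegraph
    processes, an overdamped bead-spring chain simulator, and ideal
    peptide-geometry builders) supply inputs with the statistical
    structure the analysis assumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    bio3d,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
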