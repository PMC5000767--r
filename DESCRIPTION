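Package: qmmconverge
Title: Convergence Diagnostics and Efficient Conformational Sampling for
    QM/MM Barrier Averaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding how many enzyme conformations must be sampled
    when activation barriers are computed by adiabatic QM/MM calculations on
    snapshots from a molecular dynamics trajectory. Implements the
    Boltzmann-weighted (exponential) average barrier, the disproportionate
    effect of the lowest-barrier conformation, a windowed percent-change
    convergence rule applied to both statistics, and a ranked small-QM to
    big-QM pre-screening protocol with computational cost accounting.
    Includes a seeded generator of correlated synthetic barrier ensembles,
    delimited-text readers and writers for per-conformation barrier tables,
    JSON/TSV reports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    MASS,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
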