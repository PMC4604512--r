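Package: treeDenovo
Title: Decision-Tree Scored De Novo Peptide Sequencing from Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: De novo peptide sequencing for CID tandem mass spectra using
    machine-learned scoring functions. Two binary decision trees, grown by
    greedy information-gain splitting from annotated spectra, estimate the
    probability that a prefix mass is a real fragmentation site (76 features)
    and that a residue of a candidate sequence is correct (169 features). A
    two-stage search couples a dynamic program over discretized prefix masses
    with a local refinement that re-sequences low-confidence mass segments.
    Includes readers and writers for MGF and NIST MSP peak lists, a
    residue-level precision/recall evaluation protocol with a
    verifiable-residue baseline and dipeptide mass-gap accounting, and a
    configurable simulator of annotated CID spectra for training and
    benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
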