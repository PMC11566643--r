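Package: mdrb
Title: Mass Dataset Relevance Bridging of Herbal Prototypes and In Vivo Metabolites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for untargeted LC-HRMS studies of herbal
    medicines. Implements precise-and-thorough background subtraction (PATBS)
    of blank versus post-dose biological samples, and the mass dataset
    relevance bridging (MDRB) algorithm that links in vitro prototype
    components to in vivo metabolites by stepwise prototype, predictable
    (biotransformation-catalog) and unpredictable (mass-defect) matching with
    an MS2 fragment-similarity scoring mechanism. Includes a pathway catalog
    of common phase I/II reactions and glycoside losses, a ground-truth
    simulator of prototype/metabolite feature lists, network assembly and
    per-matrix exposure summaries, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
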