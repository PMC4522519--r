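Package: qpercept
Title: Quantum Instruments for Modelling Bistable Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-dimensional quantum-state algebra (density operators,
    tensor products, partial traces), quantum instruments and positive
    operator valued measures (POVMs), and the indirect-measurement scheme in
    which a consciously inaccessible sensation state is read out through a
    unitary interaction with a perception state.  Includes a sequential
    rotation protocol for bistable perception of ambiguous figures such as
    the Schroeder stair (exact path enumeration and Monte-Carlo sampling),
    Leggett-Garg-type temporal contextuality tests with a classical joint
    feasibility solver, a synthetic-experiment generator for three-group
    rotation designs, and maximum-likelihood fitting of model parameters to
    binary response curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
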