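Package: prcaudit
Title: Precision-Recall Curves and AUPRC Under Explicit Interpolation and
    Tie-Handling Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs precision-recall curves and computes the area under
    them (AUPRC) under every commonly used anchor-connection method (direct
    straight line, discrete and continuous expectation interpolation, and
    step-wise Average Precision), with explicit control over how tied
    classification scores, the curve start point, and the recall range are
    handled.  Provides named presets that emulate the method combinations of
    popular evaluation tools, diagnostics that quantify how much each choice
    inflates or perturbs the AUPRC of a given data set, brute-force oracles
    (permutation averaging, numeric quadrature, pairwise AUROC counting) for
    verification, and a synthetic score/label generator with controllable
    class imbalance, separation, and tie-block structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
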