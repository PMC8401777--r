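Package: mmpcliff
Title: Interpretable Activity-Cliff Prediction with Matched Molecular Pair Kernels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prediction of activity cliffs between matched molecular pairs
    (MMPs) with a support vector machine over the MMP kernel, the product of
    core-wise and substituent-wise Tanimoto kernels on interpretable,
    collision-free substructure fingerprints. Provides single-cut MMP
    fragmentation with size constraints, matched-molecular-series grouping,
    series-wise leave-one-out evaluation with compound-overlap elimination,
    and an exact additive decomposition of each decision value into
    per-feature contributions obtained by splitting every core-substituent
    kernel cross-term evenly between its two features. Contributions are
    mapped back onto atoms and bonds for structure colouring. A Kernel SHAP
    explainer over the same decision function is included as a
    model-independent control, together with synthetic analog-series
    generators with planted cliffs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    kernlab,
    igraph,
    pROC,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
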