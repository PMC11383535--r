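Package: memrsa
Title: Item-Wise Representational Similarity Analysis of Memory Encoding and Retrieval
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for item-wise representational similarity analysis (RSA) of
    episodic memory experiments. Builds visual and semantic model similarity
    matrices from feature norms, estimates single-trial activation patterns
    with a double-gamma general linear model, assembles temporally corrected
    activity-pattern matrices, computes item-wise RSM-activity fits (IRAFs),
    applies a false-alarm-tendency adjustment to recognition responses, fits
    crossed random-intercept mixed models with Satterthwaite degrees of
    freedom and FDR correction, decodes feature type across memory phases
    with a linear support vector machine, and estimates statistical power by
    simulation. A synthetic-study generator with planted representational
    effects provides a ground-truth test surface for the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    e1071,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
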