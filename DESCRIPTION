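Package: tensormol
Title: Alignment-Free 3D Molecular Descriptors from N-Linear Algebraic
    Forms and GA-MLR QSAR Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes alignment-free three-dimensional molecular
    descriptors by contracting two-, three- and four-tuple spatial
    (dis)similarity tensors, built from interatomic metrics and
    multi-metrics (Minkowski family, Canberra, Soergel, bond angles,
    dihedrals, volumes and others), with atomic-property vectors through
    N-linear algebraic forms.  Tensors support local-fragment projection,
    simple-stochastic, double-stochastic (Sinkhorn-Knopp) and
    mutual-probability normalizations, and entrywise Hadamard powers.
    Includes a QSAR model-building workflow: Shannon-entropy, magnitude
    and correlation descriptor thinning, genetic-algorithm variable
    selection for multiple linear regression with leave-one-out Q2 as
    fitness, bootstrap and Y-scrambling validation, and external test-set
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    ChemmineR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
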