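Package: velogrn
Title: Gene Regulatory Network Inference from Time-Stamped Single-Cell Data
    via Optimal-Transport Gene Velocities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates per-cell, per-gene velocities (rates of change of
    expression) from time-stamped single-cell expression cohorts by solving
    entropic fused Gromov-Wasserstein optimal transport problems between
    consecutive time points and applying finite differences to barycentric
    state predictions.  Signed, directed, time-resolved gene regulatory
    networks are then inferred from the velocity field by transport-weighted
    time-lagged correlation or by elastic-net Granger regression.  Includes
    a stochastic simulator of destructively sampled single-cell time courses
    driven by a known signed network (with branching, dropout and cohort
    imbalance), and signed/unsigned AUPRC, AUROC and early-precision
    benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    data.table,
    glmnet,
    igraph,
    stats,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
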