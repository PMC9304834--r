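Package: salnet
Title: Parcellation-Based Structural-Functional Modeling of Brain Networks
Version: 0.1.0
Authors@R:
    person("salnet", "maintainers", email = "maintainers@salnet.dev", role = c("aut", "cre"))
Description: Builds parcellation-based structural-functional network models of
    the human brain from published functional MRI activation coordinates.
    Implements coordinate-based activation likelihood estimation (ALE)
    meta-analysis with Monte-Carlo cluster-level inference, percentage-overlap
    selection of atlas parcels against the ALE result, deterministic streamline
    tractography on per-subject fiber orientation fields with two-ROI tract
    isolation, and connection-strength statistics (presence counts, tract-count
    averages, laterality indices, rank-sum tests, and fiber-type taxonomy).
    A synthetic-data module generates foci tables, label volumes, and
    multi-subject orientation fields with planted fiber bundles so the whole
    pipeline can be exercised end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
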