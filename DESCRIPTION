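Package: msot
Title: Multistage Optimal Transport for Trajectory Inference from
    Single-Cell Snapshots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers pseudotime, cell-cell transition probabilities, fate
    probabilities and outlier cells from a single snapshot of single-cell
    data with user-designated initial and terminal states.  The snapshot
    is modelled as a multistage, entropy-regularized optimal transport
    process over a fixed number of latent differentiation stages, solved
    by generalized Sinkhorn scaling with inequality marginals nested in a
    proximal point scheme.  Includes an inverse-distance-weighted baseline
    predictor, clonal lineage-tracing benchmark metrics, and a seeded
    generator of branching two-dimensional snapshots for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
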