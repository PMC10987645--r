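Package: atomscreen
Title: Structure-Based Virtual Screening with Graph-Convolutional Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end desk-scale virtual screening workflow for
    protein-ligand complexes. Prepares screening libraries by drug-likeness
    and structural-alert filtering and by chemotype-novelty exclusion against
    known binders of a target and its sequence homologs; converts receptor
    structures and docked ligand poses into distance-annotated atom graphs
    with Sybyl atom typing; scores complexes with a five-block multi-task
    graph-convolutional network trained as an ensemble over
    sequence-identity-clustered folds; turns ranked scores into diverse,
    audit-trailed compound selections via Butina clustering and blinded
    assay plates; expands confirmed hits with fingerprint nearest-neighbor
    and substructure analog searches; and computes screening-campaign
    hit-rate statistics. Ships a synthetic-fixture generator (toy pockets,
    poses, planted structure-activity labels) so the full pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Biostrings,
    ChemmineR,
    ChemmineOB,
    bio3d,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
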