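Package: moaclust
Title: Mechanism-of-Action Prediction by Maximal-Dissimilarity Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based prediction of where in the NF-kB signalling pathway a
    small molecule acts. A labelled compound library is clustered by maximal
    dissimilarity partitioning under one of seven 2D descriptor sets (circular
    fingerprints, physicochemical properties, BCUT/GCUT eigenvalue descriptors
    and their combinations), clusters are annotated with the predominant
    interaction class of their members, and query compounds inherit the label
    of their most similar cluster, with optional abstention below a similarity
    threshold. Includes a synthetic compound-library generator (SMILES scaffold
    series and abstract fingerprint space) and an orchestration layer running
    the full training/test protocol across descriptor sets and clustering
    seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
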