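Package: rxnsearch
Title: Feedback-Driven Chemical Reaction Search with Contrastive Graph Embeddings
Version: 0.1.0
Authors@R: person("rxnsearch", "developers", role = c("aut", "cre"),
    email = "rxnsearch@example.org")
Description: An intelligent chemical reaction search system. Reaction records
    (reactants, optional reagents, one product, numeric conditions) are embedded
    with a shared graph isomorphism network encoder and role-specific projection
    heads trained by a Euclidean NT-Xent contrastive objective, compressed with
    an uncentered principal-component basis, and retrieved by Euclidean top-K
    search with attribute-range filtering. Binary relevance ratings on retrieved
    records drive human-in-the-loop fine-tuning via a margin ranking loss blended
    with the contrastive objective, after which the database is re-embedded.
    Includes a synthetic reaction-dataset generator, product-prediction metrics
    (MRR, MR, Hit@k), simulated user-preference feedback experiments, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    data.table,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
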