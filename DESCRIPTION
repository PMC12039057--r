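Package: spectrasig
Title: Skeleton-Specific MS/MS Spectral Signatures and MassQL Queries
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts diagnostic fragment-ion and neutral-loss signatures
    from annotated MS/MS spectral libraries in which each spectrum carries an
    expert-assigned structural skeleton label. Candidate signals are scored per
    skeleton group with an F2 statistic, additive signal combinations are
    evaluated against the raw library with an F0.5 statistic, and the winning
    conjunctive queries are serialized as MassQL statements that can be applied
    to feature-level MGF datasets. Supporting analyses include Morgan
    fingerprint Tanimoto similarity between skeleton scaffolds with
    dendrogram-based leaf ordering, modified cosine and classic cosine spectral
    similarity matrices, retrieval evaluation metrics, genus-level source
    attribution summaries, and a ground-truthed synthetic library generator
    used for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
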