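Package: FlavoPredict
Title: Enzyme-Promiscuity Prediction of Gut Bacterial Flavonoid Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts gut-bacterial metabolites of dietary flavonoids from
    enzyme promiscuity. Atom-group transformation operators (a reaction-center
    atom plus its first- and second-shell neighbourhood, with an edit script)
    are derived from atom-mapped reactant-product pairs and applied to
    non-natural substrates in a two-round, filtered prediction pipeline.
    Candidate enzymes are mapped to organisms and taxa through an organism by
    EC-number incidence matrix at three-digit EC resolution, reaction pairs are
    clustered by atom-pair Tanimoto similarity to nominate ring-cleavage
    enzymes, and protein sets are screened for chalcone-synthase-like homologs
    by global percent identity with a neighbour-joining tree. Seeded synthetic
    generators (reaction corpora with planted operators, strain-enzyme
    matrices, mutated homolog sets) let the whole analysis run offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    Biostrings,
    ape,
    vegan
Suggests:
    testthat (>= 3.0.0),
    ChemmineR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
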