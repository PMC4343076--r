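Package: annsim
Title: Annotation-Based Semantic Similarity via Maximum-Weight Bipartite Matching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes AnnSim, a general-purpose similarity measure for
    scientific entities (drugs, proteins, diseases) annotated with terms
    from an ontology. AnnSim scores a pair of entities by solving the
    exact 1-1 maximum-weight bipartite matching between their annotation
    sets, with edge weights given by taxonomic term similarities
    (1 - d_tax, 1 - d_ps) on the ontology DAG, and normalizing the optimal
    matching weight Dice-style by the two set cardinalities. Also provides
    the underlying ontology machinery (depth, shortest ancestor distances,
    greatest-depth lowest common ancestors on rooted DAGs, with OBO and
    edge-list readers), the HeteSim relevance-path relatedness measure on
    typed heterogeneous graphs as a comparison baseline, a suite of
    evaluation statistics (nDCG, Pearson/Spearman correlation with
    Fisher-z significance, Jaccard indices, a pair-counting clustering
    agreement index, Davies-Bouldin cluster validity in two variants, and
    a centroid-coupling measure), and seeded synthetic generators for
    ontologies, annotation graphs, category maps and clusterings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
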