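test_that("generator_config validates its ranges", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(n_terms = 1L), "at least 2")
  expect_error(generator_config(annotation_size_range = c(5L, 2L)), "min <= max")
  expect_error(generator_config(subtree_bias = 1.5), "\\[0, 1\\]")
  expect_error(generator_config(n_entities = 0L), "positive")
})

test_that("gen_ontology is deterministic, rooted and shape-controlled", {
  cfg <- generator_config(seed = 3L, n_terms = 200L, max_parents = 3L,
                          target_depth = 8L)
  g1 <- gen_ontology(cfg)
  g2 <- gen_ontology(cfg)
  expect_identical(g1$edges, g2$edges)
  expect_identical(g1$roots, "root")
  expect_identical(length(g1$terms), 200L)

  # every term reaches the root (constructor also enforces acyclicity)
  for (x in sample(g1$terms, 20L)) {
    expect_true("root" %in% oracle_ancestors(g1, x))
  }
  expect_identical(max(g1$depth), 8L)

  tree <- gen_ontology(generator_config(seed = 4L, n_terms = 50L,
                                        max_parents = 1L))
  expect_identical(anyDuplicated(tree$edges[, 1L]), 0L)  # single parents
})

test_that("ontology invariants hold across many random configs", {
  for (seed in 1:20) {
    cfg <- generator_config(seed = seed,
                            n_terms = sample(10:120, 1L),
                            max_parents = sample(1:4, 1L),
                            target_depth = sample(2:9, 1L))
    g <- gen_ontology(cfg)
    expect_identical(g$roots, "root")
    expect_identical(anyDuplicated(paste(g$edges[, 1L], g$edges[, 2L])), 0L)
    expect_false(any(g$edges[, 1L] == g$edges[, 2L]))
    expect_true(all(g$depth[setdiff(g$terms, "root")] >= 1L))
  }
})

test_that("gen_annotations respects sizes, terms and determinism", {
  cfg <- generator_config(seed = 9L, n_terms = 60L, n_entities = 12L,
                          annotation_size_range = c(1L, 1L))
  G <- gen_ontology(cfg)
  AG <- gen_annotations(G, cfg)
  expect_true(all(lengths(AG$annotations) == 1L))

  cfg2 <- generator_config(seed = 9L, n_terms = 60L, n_entities = 12L,
                           annotation_size_range = c(2L, 7L))
  AG2 <- gen_annotations(G, cfg2)
  expect_true(all(lengths(AG2$annotations) >= 2L &
                  lengths(AG2$annotations) <= 7L))
  expect_identical(gen_annotations(G, cfg2)$annotations, AG2$annotations)
  expect_true(all(unlist(AG2$annotations) %in% G$terms))

  cfg_bad <- generator_config(seed = 1L, n_terms = 5L,
                              annotation_size_range = c(1L, 50L))
  expect_error(gen_annotations(gen_ontology(cfg_bad), cfg_bad), "exceeds")
})

test_that("subtree-biased families have higher within-family annsim", {
  wins <- 0L
  for (seed in 1:20) {
    cfg <- generator_config(seed = seed, n_terms = 150L, max_parents = 2L,
                            target_depth = 7L, n_entities = 8L,
                            annotation_size_range = c(3L, 6L),
                            n_families = 2L, subtree_bias = 1)
    G <- gen_ontology(cfg)
    AG <- gen_annotations(G, cfg)
    fam <- attr(AG, "family")
    M <- pairwise_annsim(AG)
    same <- outer(fam, fam, "==")
    off <- upper.tri(M)
    within <- mean(M[off & same])
    across <- mean(M[off & !same])
    if (within > across) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("gen_categories and the identical-set clustering line up", {
  cfg <- generator_config(seed = 2L, n_entities = 20L, n_categories = 6L,
                          category_sets_per_entity = c(1L, 2L))
  cats <- gen_categories(cfg)
  expect_identical(gen_categories(cfg), cats)
  expect_length(cats, 20L)
  clu <- cluster_by_identical_categories(cats)
  key <- vapply(cats, function(s) paste(sort(s), collapse = "|"), character(1))
  for (pair in utils::combn(names(cats), 2L, simplify = FALSE)) {
    expect_identical(clu[[pair[1L]]] == clu[[pair[2L]]],
                     key[[pair[1L]]] == key[[pair[2L]]])
  }
})

test_that("write_synthetic_dataset round-trips through the loaders", {
  cfg <- generator_config(seed = 6L, n_terms = 50L, n_entities = 10L,
                          annotation_size_range = c(1L, 5L))
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(cfg, dir)
  G <- load_ontology_edges(paths[["ontology"]])
  expect_identical(G$edges[order(G$edges[, 1L], G$edges[, 2L]), ],
                   with(list(e = gen_ontology(cfg)$edges),
                        e[order(e[, 1L], e[, 2L]), ]),
                   ignore_attr = TRUE)
  AG <- load_annotations(paths[["annotations"]], G)
  expect_identical(AG$annotations, gen_annotations(gen_ontology(cfg), cfg)$annotations)
  clu <- load_clustering(paths[["clustering"]])
  cats <- load_categories(paths[["categories"]])
  expect_setequal(names(clu), names(cats))
})

test_that("worked fixtures have the documented structure", {
  fix <- worked_fixtures()
  expect_identical(fix$chain$ontology$roots, "root")
  expect_identical(root_distance(fix$chain$ontology, "x"), 5L)
  expect_identical(root_distance(fix$shortcut_dag$ontology, "y"), 3L)
  expect_identical(term_lca(fix$shortcut_dag$ontology, "x", "y"), "L")
  sizes <- table(fix$gold_clustering$clustering)
  expect_gte(sum(sizes >= 2L), 1L)
  expect_gte(sum(sizes == 1L), 5L)
})
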