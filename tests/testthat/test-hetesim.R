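ann_path <- c("annotates", "identity", "annotated_by")

make_ann_graph <- function(sets) {
  terms <- sort(unique(unlist(sets)))
  nodes <- data.frame(id = c(names(sets), terms),
                      type = c(rep("entity", length(sets)),
                               rep("term", length(terms))))
  edges <- do.call(rbind, lapply(names(sets), function(e) {
    if (!length(sets[[e]])) return(NULL)
    cbind(e, sets[[e]])
  }))
  H <- hetero_graph(nodes, list(
    annotates = list(from = "entity", to = "term", edges = edges),
    annotated_by = list(from = "term", to = "entity",
                        edges = edges[, 2:1, drop = FALSE])
  ))
  add_identity_relation(H, "term")
}

test_that("hetesim unrolls the annotation meta-path correctly", {
  # disjoint 3-vs-7 term sets: strict exact-match baseline gives 0
  H0 <- make_ann_graph(list(s = paste0("A", 1:3), t = paste0("B", 1:7)))
  expect_equal(hetesim(H0, "s", "t", ann_path), 0)

  H1 <- make_ann_graph(list(s = "T1", t = "T1"))
  expect_equal(hetesim(H1, "s", "t", ann_path), 1)

  H2 <- make_ann_graph(list(s = "T1", t = c("T1", "T2")))
  expect_equal(hetesim(H2, "s", "t", ann_path), 0.5)

  # general overlap: |A1 n A2| / (|A1| |A2|)
  H3 <- make_ann_graph(list(s = c("T1", "T2", "T3"), t = c("T2", "T3", "T4", "T5")))
  expect_equal(hetesim(H3, "s", "t", ann_path), 2 / 12)
})

test_that("path construction enforces type compatibility; ends are type-checked", {
  H <- make_ann_graph(list(s = "T1", t = "T2"))
  expect_error(relevance_path(H, c("annotates", "annotates")), "type mismatch")
  expect_error(relevance_path(H, "no_such_rel"), "unknown relation")
  expect_error(relevance_path(H, character()), "at least one")
  expect_error(hetesim(H, "T1", "t", ann_path), "type")
  expect_error(hetesim(H, "s", "T2", ann_path), "type")
  expect_error(hetesim(H, "zz", "t", ann_path), "unknown node")
})

test_that("empty neighbor sets yield 0, not an error", {
  sets <- list(s = "T1", t = character())
  H <- make_ann_graph(list(s = "T1", lone = "T2"))
  # 'lone' has annotations but an entity with none scores 0 against all
  nodes <- rbind(H$nodes, data.frame(id = "bare", type = "entity"))
  H2 <- hetero_graph(nodes, H$relations)
  expect_equal(hetesim(H2, "bare", "s", ann_path), 0)
  expect_equal(hetesim(H2, "s", "bare", ann_path), 0)
})

test_that("hetesim equals the random-walk meeting-probability oracle", {
  for (seed in 1:25) {
    H <- random_annotation_hetgraph(seed, n_ent = sample(3:6, 1L),
                                    n_term = sample(5:20, 1L))
    ents <- H$nodes$id[H$nodes$type == "entity"]
    pairs <- t(utils::combn(ents, 2L))
    for (k in seq_len(min(6L, nrow(pairs)))) {
      s <- pairs[k, 1L]; t_ <- pairs[k, 2L]
      got <- hetesim(H, s, t_, ann_path)
      expect_equal(got, oracle_hetesim(H, s, t_, ann_path), tolerance = 1e-12)
      expect_gte(got, 0); expect_lte(got, 1)
      # even-length path variant exercises the l = 2 peel
      got2 <- hetesim(H, s, t_, c("annotates", "annotated_by"))
      expect_equal(got2, oracle_hetesim(H, s, t_, c("annotates", "annotated_by")),
                   tolerance = 1e-12)
    }
  }
})

test_that("hetesim is symmetric under path reversal with inverse relations", {
  for (seed in 1:8) {
    H <- random_annotation_hetgraph(seed)
    ents <- H$nodes$id[H$nodes$type == "entity"]
    rev_path <- c("annotates", "identity", "annotated_by")  # self-inverse path
    for (k in 1:5) {
      p <- sample(ents, 2L)
      expect_equal(hetesim(H, p[1L], p[2L], ann_path),
                   hetesim(H, p[2L], p[1L], rev_path))
    }
  }
})

test_that("growing the overlap at fixed set sizes never decreases hetesim", {
  # |A1 n A2| / (|A1||A2|) with sizes held fixed is monotone in the overlap
  base <- paste0("T", 1:8)
  for (ov in 0:3) {
    s_set <- c(base[seq_len(ov)], paste0("S", seq_len(4 - ov)))
    t_set <- c(base[seq_len(ov)], paste0("U", seq_len(4 - ov)))
    H <- make_ann_graph(list(s = s_set, t = t_set))
    val <- hetesim(H, "s", "t", ann_path)
    expect_equal(val, ov / 16)
    if (ov > 0) expect_gt(val, (ov - 1) / 16)
  }
})

test_that("graph files round-trip through load_hetero_graph", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# annotation graph",
    "@node\ts\tentity", "@node\tt\tentity",
    "@node\tT1\tterm", "@node\tT2\tterm",
    "@relation\tannotates\tentity\tterm",
    "@relation\tannotated_by\tterm\tentity",
    "@relation\tidentity\tterm\tterm",
    "annotates\ts\tT1", "annotates\tt\tT1", "annotates\tt\tT2",
    "annotated_by\tT1\ts", "annotated_by\tT1\tt", "annotated_by\tT2\tt",
    "identity\tT1\tT1", "identity\tT2\tT2"
  ), f)
  H <- load_hetero_graph(f)
  expect_equal(hetesim(H, "s", "t", ann_path), 0.5)
  writeLines(c("@node\ta\tentity", "mystery\ta\ta"), f)
  expect_error(load_hetero_graph(f), "undeclared")
})
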