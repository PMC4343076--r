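test_that("ndcg matches hand-computed discounted gains", {
  # perfect ranking
  expect_equal(ndcg(c("a", "b", "c"), c(0.9, 0.5, 0.1), c(3, 2, 1)), 1)
  expect_equal(ndcg("only", 0.3, 2), 1)

  # relevance (3,2,1) presented by scores in order (1,3,2):
  # DCG = 1 + 3/1 + 2/log2(3); ideal = 3 + 2 + 1/log2(3)
  got <- ndcg(c("i1", "i2", "i3"), scores = c(0.9, 0.5, 0.2),
              relevance = c(1, 3, 2))
  dcg <- 1 + 3 / 1 + 2 / log2(3)
  ideal <- 3 + 2 / 1 + 1 / log2(3)
  expect_equal(got, dcg / ideal)
  expect_equal(round_to(got, 4), 0.9345)

  # score ties resolve by item ID, so permuting tied input rows is neutral
  expect_equal(ndcg(c("a", "b", "c"), c(0.5, 0.5, 0.5), c(1, 2, 3)),
               ndcg(c("c", "a", "b"), c(0.5, 0.5, 0.5), c(3, 1, 2)))
  expect_error(ndcg(c("a", "b"), c(1, 2), c(0, 0)), "all-zero")
})

test_that("correlations agree with direct rank arithmetic", {
  x <- c(1, 2, 3, 4)
  expect_equal(score_correlation(x, x, "pearson"), 1)
  expect_equal(score_correlation(x, -x, "spearman"), -1)
  # hand rank formula: d = (1-2, 2-1, 3-4, 4-3), 1 - 6*sum(d^2)/(n(n^2-1))
  expect_equal(score_correlation(x, c(2, 1, 4, 3), "spearman"),
               1 - 6 * 4 / (4 * 15))
  # pearson is invariant under positive affine maps
  y <- c(0.2, 1.4, 0.9, 2.2)
  expect_equal(score_correlation(x, y, "pearson"),
               score_correlation(3 * x + 7, 0.5 * y - 1, "pearson"))
  expect_error(score_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(score_correlation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("fisher z-test matches the closed form and detects strong gaps", {
  expect_equal(fisher_z_test(0.4, 0.4, 50)$p, 1)
  expect_equal(fisher_z_test(0.5, 0, 103)$z, atanh(0.5) * 10)
  # a 0.6510-vs-0.2164 correlation gap at benchmark scale is significant
  expect_lt(fisher_z_test(0.6510, 0.2164, 1000)$p, 0.01)
  expect_error(fisher_z_test(1, 0.2, 10), "strictly inside")
  expect_error(fisher_z_test(0.5, 0.2, 3), "exceed 3")
})

test_that("jaccard_set and category_score follow pooled pair counting", {
  expect_equal(jaccard_set(1:3, 1:3), 1)
  expect_equal(jaccard_set(1:2, 3:4), 0)
  expect_equal(jaccard_set(1:3, 2:4), 0.5)
  expect_error(jaccard_set(character(), character()), "empty")

  cats <- list(A = c("k1"), B = c("k1"), C = c("k1", "k2"), D = c("k1", "k3"),
               E = "k9")
  clu <- c(A = "c1", B = "c1", C = "c2", D = "c2", E = "c3")
  # pairs: (A,B) jaccard 1, (C,D) jaccard 1/3; singleton E contributes none
  expect_equal(category_score(clu, cats), mean(c(1, 1 / 3)))
  clu2 <- c(A = "c1", B = "c2", C = "c3", D = "c4", E = "c5")
  expect_error(category_score(clu2, cats), "two or more")
  # disjoint categories in one cluster
  expect_equal(category_score(c(A = "c", E = "c"), cats), 0)
})

test_that("pair-counting jaccard agreement between partitions", {
  c1 <- c(a = 1, b = 1, c = 1, d = 1)
  c2 <- c(a = "x", b = "x", c = "y", d = "y")
  # n11 = 2 (ab, cd), n10 = 4 (ac, ad, bc, bd), n01 = 0
  expect_equal(jaccard_clustering(c1, c2), 1 / 3)
  expect_equal(jaccard_clustering(c2, c1), 1 / 3)
  expect_equal(jaccard_clustering(c1, c1), 1)
  singletons <- c(a = 1, b = 2, c = 3, d = 4)
  expect_equal(jaccard_clustering(singletons, setNames(4:1, letters[1:4])), 1)
  expect_error(jaccard_clustering(c1, c(a = 1, z = 2)), "different entity sets")

  # random partitions against an independent co-membership recount
  set.seed(5)
  for (r in 1:10) {
    n <- sample(4:9, 1L)
    p1 <- setNames(sample(1:3, n, TRUE), paste0("e", 1:n))
    p2 <- setNames(sample(1:3, n, TRUE), paste0("e", 1:n))
    co <- function(p) outer(p, p, "==")[upper.tri(diag(n))]
    a <- co(p1[sort(names(p1))]); b <- co(p2[sort(names(p2))])
    expected <- if (sum(a | b) == 0) 1 else sum(a & b) / sum(a | b)
    expect_equal(jaccard_clustering(p1, p2), expected)
    expect_equal(jaccard_clustering(p1, p2), jaccard_clustering(p2, p1))
  }
})

test_that("davies_bouldin reproduces hand geometry in both variants", {
  f <- rbind(p1 = c(0, 0), p2 = c(0, 2), q1 = c(10, 0), q2 = c(10, 2))
  clu <- c(p1 = "A", p2 = "A", q1 = "B", q2 = "B")
  expect_equal(davies_bouldin(f, clu, variant = "standard"), 0.2)
  expect_equal(davies_bouldin(f, clu, variant = "centroid_scatter"),
               2 / sqrt(101))

  # singleton clusters at distinct points: zero scatter, index 0
  f2 <- rbind(a = c(0, 0), b = c(3, 4))
  clu2 <- c(a = "A", b = "B")
  expect_equal(davies_bouldin(f2, clu2, variant = "standard"), 0)
  expect_equal(davies_bouldin(f2, clu2, variant = "centroid_scatter"), 0)

  # coincident centroids are degenerate
  f3 <- rbind(a = c(1, 1), b = c(1, 1))
  expect_error(davies_bouldin(f3, c(a = "A", b = "B"), variant = "standard"),
               "degenerate")
  expect_error(davies_bouldin(f, c(p1 = "A", p2 = "A", q1 = "A", q2 = "A")),
               "two clusters")
})

test_that("standard davies_bouldin falls as clusters move apart, shapes fixed", {
  clu <- c(p1 = "A", p2 = "A", q1 = "B", q2 = "B")
  vals <- vapply(c(5, 10, 20, 40), function(sep) {
    f <- rbind(p1 = c(0, 0), p2 = c(0, 2), q1 = c(sep, 0), q2 = c(sep, 2))
    davies_bouldin(f, clu, variant = "standard")
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("coupling averages pairwise centroid cosines", {
  f <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 1))
  clu <- c(a = "A", b = "B", c = "C")
  expect_equal(coupling(f, clu), (0 + 1 / sqrt(2) + 1 / sqrt(2)) / 3)
  expect_equal(round_to(coupling(f, clu), 4), 0.4714)

  f2 <- rbind(a = c(2, 2), b = c(1, 1))
  expect_equal(coupling(f2, c(a = "A", b = "B")), 1)
  expect_error(coupling(rbind(a = c(0, 0), b = c(1, 1)),
                        c(a = "A", b = "B")), "zero-norm")
})

test_that("clustering/category/feature files load as declared", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("e1\tc1", "e2\tc1", "e3\tc2"), f)
  expect_equal(load_clustering(f), c(e1 = "c1", e2 = "c1", e3 = "c2"))
  writeLines(c("e1\tc1", "e1\tc2"), f)
  expect_error(load_clustering(f), "more than one cluster")

  writeLines(c("e1\tcatA", "e1\tcatB", "e2\tcatA"), f)
  expect_equal(load_categories(f), list(e1 = c("catA", "catB"), e2 = "catA"))

  writeLines(c("e1\t0.5\t1.5", "e2\t2\t3"), f)
  m <- load_feature_matrix(f)
  expect_equal(m, matrix(c(0.5, 2, 1.5, 3), 2, 2,
                         dimnames = list(c("e1", "e2"), NULL)),
               ignore_attr = TRUE)
  expect_identical(rownames(m), c("e1", "e2"))
})
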