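#' Normalized discounted cumulative gain
#'
#' Rank-quality statistic comparing the ranking induced by a similarity
#' measure's scores against graded ground-truth relevance. Items are
#' sorted by descending score (ties broken by item ID for determinism)
#' and the discounted cumulative gain
#' \deqn{DCG = rel_1 + \sum_{i \ge 2} rel_i / \log_2 i}
#' is divided by the DCG of the ideal (relevance-sorted) ranking. A
#' value near 1 means the scores rank items almost as the ground truth
#' does. Linear gain with the classic undiscounted first position is the
#' default; `exponential_gain = TRUE` substitutes `2^rel - 1` gains.
#'
#' @param items character vector of item IDs.
#' @param scores numeric scores of the measure under evaluation.
#' @param relevance non-negative ground-truth grades (same length); at
#'   least one must be positive.
#' @param exponential_gain use `2^rel - 1` instead of linear gain.
#' @return A number in `(0, 1]`.
#' @export
ndcg <- function(items, scores, relevance, exponential_gain = FALSE) {
  if (length(items) != length(scores) || length(items) != length(relevance)) {
    stop("items, scores and relevance must have the same length", call. = FALSE)
  }
  if (any(relevance < 0)) stop("relevance must be non-negative", call. = FALSE)
  if (all(relevance == 0)) {
    stop("all-zero relevance: nDCG undefined", call. = FALSE)
  }
  gain <- if (exponential_gain) 2^relevance - 1 else relevance
  dcg <- function(g) {
    i <- seq_along(g)
    disc <- c(1, log2(i[-1L]))
    sum(g / disc)
  }
  ord <- order(-scores, items)
  ideal <- order(-gain)
  dcg(gain[ord]) / dcg(gain[ideal])
}

#' Correlation between two score vectors
#'
#' Pearson product-moment or Spearman rank correlation (mid-ranks for
#' ties, the convention needed when similarity tables repeat values
#' heavily). Thin validated front-end over [stats::cor()].
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @param method `"pearson"` or `"spearman"`.
#' @return A number in `[-1, 1]`.
#' @export
score_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have the same length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(x, y, method = method)
}

#' Fisher z-test comparing a correlation against a reference value
#'
#' One-sample z-test for a correlation coefficient: both coefficients
#' are mapped through Fisher's variance-stabilizing transform
#' `z = atanh(r)`, the difference is scaled by `sqrt(n - 3)`, and a
#' two-sided p-value is taken from the standard normal. Used to ask
#' whether one measure's correlation with a gold standard could have
#' arisen under another measure's correlation strength.
#'
#' @param r_obs observed correlation (|r| < 1).
#' @param r_ref reference correlation (|r| < 1).
#' @param n sample size behind the correlations (> 3).
#' @return List with `z` (statistic) and `p` (two-sided p-value).
#' @export
fisher_z_test <- function(r_obs, r_ref, n) {
  if (abs(r_obs) >= 1 || abs(r_ref) >= 1) {
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  }
  if (n <= 3) stop("n must exceed 3", call. = FALSE)
  z <- (atanh(r_obs) - atanh(r_ref)) * sqrt(n - 3)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Jaccard index of two sets
#'
#' `|a ∩ b| / |a ∪ b|`; the category-overlap building block.
#'
#' @param a,b vectors treated as sets; not both empty.
#' @return A number in `[0, 1]`.
#' @export
jaccard_set <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) stop("both sets are empty", call. = FALSE)
  length(intersect(a, b)) / u
}

#' Average category-based score of a clustering
#'
#' Mean Jaccard index of the category sets over all unordered
#' within-cluster entity pairs, pooled across clusters. Singleton
#' clusters contribute no pairs (and so do not dilute the score); a
#' clustering that groups entities exactly when their category sets are
#' identical scores 1.
#'
#' @param clustering named vector (or list) mapping entity ID to cluster
#'   label.
#' @param categories named list mapping entity ID to its category set.
#' @return A number in `[0, 1]`.
#' @export
category_score <- function(clustering, categories) {
  clustering <- unlist(clustering)
  members <- split(names(clustering), as.character(clustering))
  total <- 0; npairs <- 0L
  for (mem in members) {
    if (length(mem) < 2L) next
    pr <- utils::combn(mem, 2L)
    for (k in seq_len(ncol(pr))) {
      e1 <- pr[1L, k]; e2 <- pr[2L, k]
      if (is.null(categories[[e1]]) || is.null(categories[[e2]])) {
        stop(sprintf("missing category set for entity '%s'",
                     if (is.null(categories[[e1]])) e1 else e2), call. = FALSE)
      }
      total <- total + jaccard_set(categories[[e1]], categories[[e2]])
      npairs <- npairs + 1L
    }
  }
  if (npairs == 0L) {
    stop("no cluster contains two or more entities", call. = FALSE)
  }
  total / npairs
}

#' Pair-counting Jaccard agreement of two clusterings
#'
#' Over all unordered entity pairs, counts pairs co-clustered in both
#' partitions (`n11`) and pairs co-clustered in exactly one (`n10`,
#' `n01`); returns `n11 / (n11 + n10 + n01)`. When no pair is
#' co-clustered anywhere (all-singleton partitions) the partitions'
#' co-membership relations are identical and the index is defined as 1.
#'
#' @param c1,c2 named vectors mapping the same entities to cluster
#'   labels.
#' @return A number in `[0, 1]`.
#' @export
jaccard_clustering <- function(c1, c2) {
  c1 <- unlist(c1); c2 <- unlist(c2)
  if (!setequal(names(c1), names(c2))) {
    stop("the two clusterings cover different entity sets", call. = FALSE)
  }
  ents <- sort(names(c1))
  if (length(ents) < 2L) return(1)
  a <- as.character(c1[ents]); b <- as.character(c2[ents])
  pr <- utils::combn(seq_along(ents), 2L)
  same1 <- a[pr[1L, ]] == a[pr[2L, ]]
  same2 <- b[pr[1L, ]] == b[pr[2L, ]]
  n11 <- sum(same1 & same2)
  n10 <- sum(same1 & !same2)
  n01 <- sum(!same1 & same2)
  if (n11 + n10 + n01 == 0L) return(1)
  n11 / (n11 + n10 + n01)
}

cluster_centroids <- function(features, clustering) {
  features <- as.matrix(features)
  if (is.null(rownames(features))) {
    stop("feature matrix needs entity row names", call. = FALSE)
  }
  clustering <- unlist(clustering)
  missing <- setdiff(names(clustering), rownames(features))
  if (length(missing)) {
    stop(sprintf("entities without feature vectors: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  members <- split(names(clustering), as.character(clustering))
  cent <- t(vapply(members, function(mem) {
    colMeans(features[mem, , drop = FALSE])
  }, numeric(ncol(features))))
  list(members = members, centroids = cent)
}

#' Davies-Bouldin cluster-validity index
#'
#' Ratio-style validity index: for each cluster the worst-case ratio of
#' summed within-cluster scatter to between-cluster separation is
#' averaged over clusters,
#' \deqn{DB = \frac{1}{k} \sum_i \max_{j \ne i} \frac{d_i + d_j}{d_{ij}}}
#' with `d_i` the mean Euclidean distance of cluster i's points to its
#' centroid. Two separations are offered: `variant = "centroid_scatter"`
#' takes `d_ij` as the mean distance of cluster i's points to centroid j
#' (the form some reports print), while `variant = "standard"` uses the
#' textbook centroid-to-centroid distance. Lower is better.
#'
#' @param features numeric matrix with entity row names.
#' @param clustering named vector mapping entity to cluster label
#'   (k >= 2 clusters).
#' @param variant `"centroid_scatter"` (default) or `"standard"`.
#' @return A non-negative number.
#' @export
davies_bouldin <- function(features, clustering,
                           variant = c("centroid_scatter", "standard")) {
  variant <- match.arg(variant)
  cc <- cluster_centroids(features, clustering)
  k <- length(cc$members)
  if (k < 2L) stop("need at least two clusters", call. = FALSE)
  features <- as.matrix(features)
  d_i <- vapply(seq_len(k), function(i) {
    pts <- features[cc$members[[i]], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2L, cc$centroids[i, ])^2)))
  }, numeric(1))

  sep <- function(i, j) {
    if (variant == "standard") {
      sqrt(sum((cc$centroids[i, ] - cc$centroids[j, ])^2))
    } else {
      pts <- features[cc$members[[i]], , drop = FALSE]
      mean(sqrt(rowSums(sweep(pts, 2L, cc$centroids[j, ])^2)))
    }
  }
  per_cluster <- vapply(seq_len(k), function(i) {
    ratios <- vapply(setdiff(seq_len(k), i), function(j) {
      dij <- sep(i, j)
      if (dij == 0) {
        stop(sprintf("degenerate separation between clusters '%s' and '%s'",
                     names(cc$members)[i], names(cc$members)[j]), call. = FALSE)
      }
      (d_i[i] + d_i[j]) / dij
    }, numeric(1))
    max(ratios)
  }, numeric(1))
  mean(per_cluster)
}

#' Coupling: mean cosine similarity between cluster centroids
#'
#' Averages the cosine similarity over all unordered centroid pairs;
#' lower values indicate better-separated clusters.
#'
#' @inheritParams davies_bouldin
#' @return A number in `[-1, 1]`.
#' @export
coupling <- function(features, clustering) {
  cc <- cluster_centroids(features, clustering)
  k <- nrow(cc$centroids)
  if (k < 2L) stop("need at least two clusters", call. = FALSE)
  norms <- sqrt(rowSums(cc$centroids^2))
  if (any(norms == 0)) {
    stop("zero-norm centroid: cosine similarity undefined", call. = FALSE)
  }
  pr <- utils::combn(seq_len(k), 2L)
  cs <- vapply(seq_len(ncol(pr)), function(m) {
    i <- pr[1L, m]; j <- pr[2L, m]
    sum(cc$centroids[i, ] * cc$centroids[j, ]) / (norms[i] * norms[j])
  }, numeric(1))
  mean(cs)
}

#' Readers for clustering, category and feature-matrix TSV files
#'
#' `load_clustering()` reads `entity_id<TAB>cluster_id` into a named
#' vector; `load_categories()` reads `entity_id<TAB>category` into a
#' named list of category sets; `load_feature_matrix()` reads a numeric
#' TSV whose first column holds entity row labels (header optional via
#' `header`).
#'
#' @param path input path.
#' @return See each description.
#' @export
load_clustering <- function(path) {
  m <- read_tsv_pairs(path, what = "clustering file")
  if (nrow(m) == 0L || any(is.na(m[, 2L]))) {
    stop("clustering file must have rows entity_id<TAB>cluster_id", call. = FALSE)
  }
  if (anyDuplicated(m[, 1L])) {
    stop("an entity appears in more than one cluster", call. = FALSE)
  }
  stats::setNames(m[, 2L], m[, 1L])
}

#' @rdname load_clustering
#' @export
load_categories <- function(path) {
  m <- read_tsv_pairs(path, what = "category file")
  if (nrow(m) == 0L || any(is.na(m[, 2L]))) {
    stop("category file must have rows entity_id<TAB>category", call. = FALSE)
  }
  lapply(split(m[, 2L], m[, 1L]), unique)
}

#' @rdname load_clustering
#' @param header whether the first row names the feature columns.
#' @export
load_feature_matrix <- function(path, header = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(is.na(m))) stop("feature matrix contains missing values", call. = FALSE)
  rownames(m) <- df[[1L]]
  m
}
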