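#' Weighted bipartite graph between two annotation sets
#'
#' Builds the complete bipartite similarity graph over the Cartesian
#' product of two term sets: cell `(i, j)` holds the taxonomic
#' similarity of the i-th left term and the j-th right term. Sides are
#' sorted term IDs, so the construction is deterministic.
#'
#' @param A1,A2 non-empty character vectors of term IDs (deduplicated).
#' @param G an [ontology_dag()].
#' @param measure taxonomic similarity to use, `"tax"` or `"ps"`
#'   (see [term_similarity()]).
#' @return An object of class `bipartite_sim_graph`: list with `left`,
#'   `right` (sorted term IDs) and `weights` (|A1| x |A2| matrix in
#'   `[0, 1]`, dimnames from the terms).
#' @export
build_bipartite <- function(A1, A2, G, measure = c("tax", "ps")) {
  measure <- match.arg(measure)
  A1 <- sort(unique(as.character(A1)))
  A2 <- sort(unique(as.character(A2)))
  if (length(A1) == 0L || length(A2) == 0L) {
    stop("annotation sets must be non-empty", call. = FALSE)
  }
  check_terms(G, c(A1, A2))
  S <- term_similarity_matrix(G, union(A1, A2), measure = measure)
  structure(
    list(left = A1, right = A2,
         weights = S[A1, A2, drop = FALSE], measure = measure),
    class = "bipartite_sim_graph"
  )
}

#' Pairwise taxonomic similarity matrix over a term set
#'
#' Symmetric matrix of [term_similarity()] values for every pair of the
#' given terms, computed with shared LCA/distance tables (much faster
#' than calling the scalar function per pair).
#'
#' @param G an [ontology_dag()].
#' @param terms character vector of term IDs.
#' @inheritParams build_bipartite
#' @return A |terms| x |terms| symmetric numeric matrix with unit
#'   diagonal (for non-root terms) and term-ID dimnames.
#' @export
term_similarity_matrix <- function(G, terms, measure = c("tax", "ps")) {
  measure <- match.arg(measure)
  terms <- sort(unique(as.character(terms)))
  check_terms(G, terms)
  D <- dag_distances(G)
  rootd <- apply(D[G$roots, , drop = FALSE], 2L, min)

  n <- length(terms)
  S <- matrix(1, n, n, dimnames = list(terms, terms))
  if (n >= 1L) {
    # self-similarity under either measure is 1 except the root/root
    # d_ps degenerate case, handled by the scalar definitions
    for (t in terms) S[t, t] <- term_similarity(G, t, t, measure)
  }
  if (n < 2L) return(S)
  anc_fin <- is.finite(D[, terms, drop = FALSE])
  for (i in 1:(n - 1L)) {
    x <- terms[i]
    for (j in (i + 1L):n) {
      y <- terms[j]
      common <- G$terms[anc_fin[, i] & anc_fin[, j]]
      dep <- G$depth[common]
      cand <- common[dep == max(dep)]
      if (length(cand) > 1L) {
        dsum <- D[cand, x] + D[cand, y]
        cand <- sort(cand[dsum == min(dsum)])
      }
      a <- cand[1L]
      dx <- D[a, x]; dy <- D[a, y]
      s <- if (measure == "tax") {
        den <- rootd[[x]] + rootd[[y]]
        if (den == 0) 1 else max(0, 1 - (dx + dy) / den)
      } else {
        rl <- rootd[[a]]
        den <- rl + dx + dy
        if (den == 0) 0 else rl / den
      }
      S[i, j] <- S[j, i] <- s
    }
  }
  S
}

#' Exact 1-1 maximum-weight bipartite matching
#'
#' Solves the assignment problem on the complete weighted bipartite
#' graph: among all 1-1 matchings that saturate the smaller side, finds
#' one whose total weight is maximal. The solver is an exact
#' Jonker-Volgenant-style shortest-augmenting-path algorithm with dual
#' potentials (O(n^2 m)); no heuristic is involved, so `total_weight` is
#' the true optimum (the optimal pairing itself need not be unique).
#'
#' @param BG a [build_bipartite()] graph, or a plain numeric weight
#'   matrix.
#' @return An object of class `annsim_matching`: list with `pairs` (a
#'   `min(n1, n2)` x 2 integer matrix of (left index, right index)),
#'   `total_weight`, and the side sizes `n1`, `n2`.
#' @export
max_weight_matching <- function(BG) {
  w <- if (inherits(BG, "bipartite_sim_graph")) BG$weights else as.matrix(BG)
  if (!is.numeric(w) || any(is.na(w))) {
    stop("weights must be a numeric matrix without NA", call. = FALSE)
  }
  n1 <- nrow(w); n2 <- ncol(w)
  flipped <- n1 > n2
  a <- if (flipped) t(w) else w
  sol <- hungarian_min(-a)
  pairs <- cbind(left = seq_len(nrow(a)), right = sol$cols)
  if (flipped) pairs <- pairs[, 2:1, drop = FALSE]
  colnames(pairs) <- c("left", "right")
  structure(
    list(pairs = pairs[order(pairs[, 1L]), , drop = FALSE],
         total_weight = sum(w[pairs]), n1 = n1, n2 = n2),
    class = "annsim_matching"
  )
}

#' @export
print.annsim_matching <- function(x, ...) {
  cat(sprintf("1-1 maximum-weight bipartite matching: %d pairs (sides %d x %d)\n",
              nrow(x$pairs), x$n1, x$n2))
  cat(sprintf("  total weight: %.6g\n", x$total_weight))
  invisible(x)
}

# Exact rectangular assignment, minimizing cost; requires nrow <= ncol.
# Shortest augmenting path with potentials (the classic O(n^2 m)
# Hungarian formulation with a virtual column 0).
hungarian_min <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n)
  v <- numeric(m + 1L)       # index j+1 for columns j = 0..m
  p <- integer(m + 1L)       # p[j+1]: row matched to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1L)
    used <- logical(m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  cols <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) cols[p[j + 1L]] <- j
  list(cols = cols)
}
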