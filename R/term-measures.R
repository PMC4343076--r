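#' Taxonomic distances between ontology terms
#'
#' Two classic path-based distances on a rooted ontology DAG, both in
#' `[0, 1]`, both built from the greatest-depth lowest common ancestor
#' (LCA) and shortest directed path lengths:
#'
#' \deqn{d_{tax}(x,y) = \frac{d(lca,x) + d(lca,y)}{d(root,x) + d(root,y)}}
#' \deqn{d_{ps}(x,y) = 1 - \frac{d(root,lca)}{d(root,lca) + d(lca,x) + d(lca,y)}}
#'
#' where `d(a, b)` is the number of edges on the shortest directed path
#' and `d(root, .)` the shortest distance from any root. `d_tax` compares
#' the climb to the LCA against the terms' overall specificity; `d_ps`
#' is small when the LCA itself sits deep below the root. Degenerate 0/0
#' cases: `d_tax(root, root) = 0` (self-distance must vanish) and
#' `d_ps(root, root) = 1` (the root is maximally general).
#'
#' LCA selection uses longest-path depth while all `d(.,.)` values are
#' shortest-path lengths; the two conventions coincide on trees but can
#' differ on multi-parent DAGs.
#'
#' @param G an [ontology_dag()].
#' @param x,y term IDs.
#' @return A number in `[0, 1]`.
#' @examples
#' # chain root->v1->v2->L with L->x1->x and L->y1->y:
#' g <- worked_fixtures()$chain$ontology
#' 1 - d_tax(g, "x", "y")  # 0.60
#' 1 - d_ps(g, "x", "y")   # 0.4286
#' @export
d_tax <- function(G, x, y) {
  geom <- term_pair_geometry(G, x, y)
  den <- geom$d_root_x + geom$d_root_y
  if (den == 0) return(0)  # x = y = a root
  # on multi-parent DAGs the greatest-depth LCA can sit farther from a
  # term (by shortest path) than the term's own root distance, pushing
  # the ratio past 1; the distance is truncated to keep [0, 1]
  min(1, (geom$d_lca_x + geom$d_lca_y) / den)
}

#' @rdname d_tax
#' @export
d_ps <- function(G, x, y) {
  geom <- term_pair_geometry(G, x, y)
  den <- geom$d_root_lca + geom$d_lca_x + geom$d_lca_y
  if (den == 0) return(1)  # x = y = a root: maximally general
  1 - geom$d_root_lca / den
}

#' LCA geometry of a term pair
#'
#' The distances entering the taxonomic measures: the LCA, its shortest
#' distances down to each term, and the shortest root distances of the
#' two terms and of the LCA.
#'
#' @inheritParams d_tax
#' @return A list with components `x`, `y`, `lca`, `d_lca_x`, `d_lca_y`,
#'   `d_root_x`, `d_root_y`, `d_root_lca`.
#' @export
term_pair_geometry <- function(G, x, y) {
  a <- term_lca(G, x, y)
  list(x = x, y = y, lca = a,
       d_lca_x = ancestor_distance(G, a, x),
       d_lca_y = ancestor_distance(G, a, y),
       d_root_x = root_distance(G, x),
       d_root_y = root_distance(G, y),
       d_root_lca = root_distance(G, a))
}

#' Taxonomic term similarity
#'
#' `1 - d` for the chosen taxonomic distance (`"tax"` or `"ps"`). These
#' are the edge weights of the bipartite annotation-matching graph.
#'
#' @inheritParams d_tax
#' @param measure `"tax"` for `1 - d_tax`, `"ps"` for `1 - d_ps`.
#' @return A number in `[0, 1]`.
#' @export
term_similarity <- function(G, x, y, measure = c("tax", "ps")) {
  measure <- match.arg(measure)
  1 - switch(measure, tax = d_tax(G, x, y), ps = d_ps(G, x, y))
}
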