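# Independent brute-force oracles used by the unit and property tests.
# They work straight off the plain edge/relation lists of the public
# data structures, never through the package's query functions.

# --- DAG oracles (path enumeration) ---------------------------------

oracle_parents <- function(G) split(G$edges[, 2L], G$edges[, 1L])
oracle_children <- function(G) split(G$edges[, 1L], G$edges[, 2L])

# all ancestors of x (x included), by climbing child->parent edges
oracle_ancestors <- function(G, x) {
  par <- oracle_parents(G)
  seen <- character(); stack <- x
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(stack, par[[v]])
  }
  sort(seen)
}

# lengths of every directed path a -> x (parent-to-child direction)
oracle_path_lengths <- function(G, a, x) {
  kids <- oracle_children(G)
  res <- integer()
  rec <- function(v, len) {
    if (v == x) res <<- c(res, len)
    for (k in kids[[v]]) rec(k, len + 1L)
  }
  rec(a, 0L)
  res
}

oracle_depth <- function(G, x) {
  max(unlist(lapply(G$roots, function(r) oracle_path_lengths(G, r, x))))
}

oracle_min_dist <- function(G, a, x) {
  lens <- oracle_path_lengths(G, a, x)
  if (!length(lens)) Inf else min(lens)
}

oracle_root_distance <- function(G, x) {
  min(vapply(G$roots, function(r) oracle_min_dist(G, r, x), numeric(1)))
}

# greatest-depth common ancestor with the package's documented
# tie-break, recomputed from enumeration
oracle_lca <- function(G, x, y) {
  common <- intersect(oracle_ancestors(G, x), oracle_ancestors(G, y))
  dep <- vapply(common, function(a) oracle_depth(G, a), numeric(1))
  cand <- common[dep == max(dep)]
  if (length(cand) > 1L) {
    dsum <- vapply(cand, function(a) {
      oracle_min_dist(G, a, x) + oracle_min_dist(G, a, y)
    }, numeric(1))
    cand <- sort(cand[dsum == min(dsum)])
  }
  cand[[1L]]
}

oracle_d_tax <- function(G, x, y) {
  a <- oracle_lca(G, x, y)
  den <- oracle_root_distance(G, x) + oracle_root_distance(G, y)
  if (den == 0) return(0)
  min(1, (oracle_min_dist(G, a, x) + oracle_min_dist(G, a, y)) / den)
}

oracle_d_ps <- function(G, x, y) {
  a <- oracle_lca(G, x, y)
  rl <- oracle_root_distance(G, a)
  den <- rl + oracle_min_dist(G, a, x) + oracle_min_dist(G, a, y)
  if (den == 0) return(1)
  1 - rl / den
}

# --- assignment oracle (exhaustive over injections) -----------------

oracle_max_matching <- function(w) {
  n <- nrow(w); m <- ncol(w)
  if (n > m) return(oracle_max_matching(t(w)))
  best <- -Inf
  rec <- function(i, used, tot) {
    if (i > n) { best <<- max(best, tot); return(invisible()) }
    for (j in setdiff(seq_len(m), used)) rec(i + 1L, c(used, j), tot + w[i, j])
  }
  rec(1L, integer(), 0)
  best
}

# --- HeteSim oracle (random-walk meeting probability) ---------------
# The source walks the first ceil(l/2) relations forward, the target
# walks the last ceil(l/2) (odd l) or l/2 (even l) relations backward;
# the oracle enumerates all walk prefixes with their uniform-branching
# probabilities and sums the product mass over meeting nodes.

oracle_hetesim <- function(H, s, t, rels) {
  o_nb <- function(rel, v) { e <- H$relations[[rel]]$edges; e[e[, 1L] == v, 2L] }
  i_nb <- function(rel, v) { e <- H$relations[[rel]]$edges; e[e[, 2L] == v, 1L] }
  merge_mass <- function(lst) {
    all <- unlist(lst)
    if (!length(all)) return(numeric())
    c(tapply(all, names(all), sum))
  }
  dist_walk <- function(v, rs, nb) {
    if (!length(rs)) return(stats::setNames(1, v))
    nbs <- nb(rs[[1L]], v)
    if (!length(nbs)) return(numeric())
    merge_mass(lapply(nbs, function(u) dist_walk(u, rs[-1L], nb) / length(nbs)))
  }
  l <- length(rels)
  fwd <- rels[seq_len(ceiling(l / 2))]
  bwd <- rels[l:(floor(l / 2) + 1L)]
  pf <- dist_walk(s, fwd, o_nb)
  pb <- dist_walk(t, bwd, i_nb)
  meet <- intersect(names(pf), names(pb))
  if (!length(meet)) return(0)
  sum(pf[meet] * pb[meet])
}

# --- random instances -----------------------------------------------

random_small_dag <- function(seed, n_max = 25L, p_extra = 0.3) {
  set.seed(seed)
  n <- sample(5:n_max, 1L)
  ids <- c("r", sprintf("n%02d", seq_len(n - 1L)))
  children <- character(); parents <- character()
  for (i in 2:n) {
    k <- 1L + stats::rbinom(1L, 2L, p_extra)
    ps <- sample.int(i - 1L, min(k, i - 1L))
    children <- c(children, rep(ids[i], length(ps)))
    parents <- c(parents, ids[ps])
  }
  ontology_dag(cbind(children, parents))
}

# annotation-style heterogeneous graph with possibly empty annotation
# sets (to exercise the zero-neighbor rule)
random_annotation_hetgraph <- function(seed, n_ent = 4L, n_term = 8L,
                                       allow_empty = TRUE) {
  set.seed(seed)
  ents <- sprintf("d%d", seq_len(n_ent))
  terms <- sprintf("T%d", seq_len(n_term))
  nodes <- data.frame(id = c(ents, terms),
                      type = c(rep("entity", n_ent), rep("term", n_term)))
  lo <- if (allow_empty) 0L else 1L
  edges <- do.call(rbind, lapply(ents, function(e) {
    k <- sample(lo:min(5L, n_term), 1L)
    if (k == 0L) return(NULL)
    cbind(e, sample(terms, k))
  }))
  if (is.null(edges)) edges <- cbind(ents[1L], terms[1L])
  H <- hetero_graph(nodes, list(
    annotates = list(from = "entity", to = "term", edges = edges),
    annotated_by = list(from = "term", to = "entity",
                        edges = edges[, 2:1, drop = FALSE])
  ))
  add_identity_relation(H, "term")
}
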