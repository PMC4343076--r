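#' Ontology DAGs
#'
#' An `ontology_dag` is a rooted directed acyclic graph of controlled
#' vocabulary terms, stored with edges pointing from child (more specific)
#' to parent (more general). It is the substrate for the taxonomic
#' distance measures: term depth (longest root-to-term path), shortest
#' ancestor distances and greatest-depth lowest common ancestors are all
#' computed against it.
#'
#' Internally the constructor validates acyclicity, deduplicates edges and
#' precomputes a topological order and the longest-path depth of every
#' term; an [igraph][igraph::igraph-package] graph oriented parent-to-child
#' backs the distance and reachability queries.
#'
#' @param edges two-column character matrix or data frame of (child,
#'   parent) pairs.
#' @param terms optional character vector of additional isolated or
#'   implied term IDs (edges already imply their endpoints).
#' @param labels optional named character vector of human-readable term
#'   names (names are term IDs).
#' @return An object of class `ontology_dag` with components `terms`
#'   (character vector, sorted), `edges` (two-column matrix child, parent),
#'   `roots` (terms with no parent), `depth` (named integer vector,
#'   longest-path depth) and `labels`.
#' @examples
#' g <- ontology_dag(cbind(c("a", "b"), c("root", "a")))
#' g$roots
#' term_depth(g, "b")
#' @seealso [load_ontology_edges()], [load_ontology_obo()], [term_lca()],
#'   [d_tax()], [d_ps()]
#' @export
ontology_dag <- function(edges, terms = character(), labels = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) != 2L) {
    stop("edges must have two columns (child, parent)", call. = FALSE)
  }
  storage.mode(edges) <- "character"
  if (any(is.na(edges))) stop("edges may not contain NA", call. = FALSE)
  if (any(edges[, 1L] == edges[, 2L])) {
    bad <- edges[edges[, 1L] == edges[, 2L], 1L][1L]
    stop(sprintf("self-loop on term '%s'", bad), call. = FALSE)
  }
  edges <- unique(edges)
  all_terms <- sort(unique(c(edges, terms)))
  if (length(all_terms) == 0L) {
    stop("ontology has no terms", call. = FALSE)
  }

  # parent -> child orientation: paths follow generalization downwards,
  # so distances(ig, a, x) is the shortest ancestor->descendant distance.
  ig <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 2L], to = edges[, 1L],
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = all_terms, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(ig)) {
    cyc <- igraph::feedback_arc_set(ig)
    member <- igraph::ends(ig, cyc[1L])[1L]
    stop(sprintf("ontology contains a cycle (involving term '%s')", member),
         call. = FALSE)
  }

  topo <- igraph::topo_sort(ig, mode = "out")$name
  has_parent <- all_terms %in% edges[, 1L]
  roots <- all_terms[!has_parent]

  # Longest-path depth by dynamic programming over the topological order.
  depth <- stats::setNames(integer(length(all_terms)), all_terms)
  parents_of <- split(edges[, 2L], edges[, 1L])
  for (v in topo) {
    p <- parents_of[[v]]
    if (!is.null(p)) depth[[v]] <- max(depth[p]) + 1L
  }

  structure(
    list(terms = all_terms, edges = edges, roots = roots,
         depth = depth, labels = labels, graph = ig,
         cache = new.env(parent = emptyenv())),
    class = "ontology_dag"
  )
}

# Full shortest-path distance matrix (ancestor rows -> descendant
# columns, Inf when unreachable), computed once per ontology. The DAG is
# immutable after construction, so memoization is safe.
dag_distances <- function(G) {
  if (is.null(G$cache$D)) {
    D <- igraph::distances(G$graph, mode = "out")
    G$cache$D <- D[G$terms, G$terms, drop = FALSE]
  }
  G$cache$D
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("Ontology DAG: %d terms, %d child->parent edges, %d root%s\n",
              length(x$terms), nrow(x$edges), length(x$roots),
              if (length(x$roots) == 1L) "" else "s"))
  cat(sprintf("  roots: %s\n",
              paste(utils::head(x$roots, 5L), collapse = ", ")))
  cat(sprintf("  max depth: %d\n", max(x$depth)))
  invisible(x)
}

#' Load an ontology from a child-parent edge list
#'
#' Reads a tab-separated file with one `child<TAB>parent` pair per line.
#' Lines starting with `#` are comments; a line with a single field
#' declares an isolated term. Duplicate edges are collapsed.
#'
#' @param path path to the edge-list TSV.
#' @return An [ontology_dag()].
#' @export
load_ontology_edges <- function(path) {
  m <- read_tsv_pairs(path, what = "ontology edge list")
  if (nrow(m) == 0L) stop("ontology edge list is empty", call. = FALSE)
  lone <- is.na(m[, 2L])
  ontology_dag(m[!lone, , drop = FALSE], terms = m[lone, 1L])
}

#' Load an ontology from an OBO file
#'
#' Parses the `[Term]` stanzas of an OBO 1.2-style file, interpreting only
#' the `id`, `name`, `is_a` and `is_obsolete` tags. Each `is_a` line
#' contributes a child-to-parent edge; stanzas marked obsolete are
#' skipped entirely. All other stanza types and tags are ignored.
#'
#' @param path path to the OBO file.
#' @return An [ontology_dag()] with `labels` filled from `name` tags.
#' @export
load_ontology_obo <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("OBO file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  # stanza boundaries
  stanza_at <- grep("^\\[", lines)
  if (length(stanza_at) == 0L) stop("no stanzas found in OBO file", call. = FALSE)
  starts <- stanza_at
  ends <- c(stanza_at[-1L] - 1L, length(lines))

  children <- character(); parents <- character()
  ids <- character(); labels <- character()

  strip <- function(x) {
    # OBO values may carry trailing '! comment' annotations
    trimws(sub("\\s*!.*$", "", x))
  }

  for (k in seq_along(starts)) {
    head_line <- trimws(lines[starts[k]])
    if (head_line != "[Term]") next
    body <- lines[seq(starts[k] + 1L, ends[k])]
    body <- body[nzchar(trimws(body))]
    id <- NULL; nm <- NULL; isa <- character(); obsolete <- FALSE
    for (off in seq_along(body)) {
      ln <- body[off]
      if (!grepl("^[A-Za-z_]+:", ln)) {
        stop(sprintf("unparseable OBO line %d: '%s'",
                     starts[k] + off, trimws(ln)), call. = FALSE)
      }
      tag <- sub(":.*$", "", ln)
      val <- strip(sub("^[A-Za-z_]+:\\s*", "", ln))
      if (tag == "id") id <- val
      else if (tag == "name") nm <- val
      else if (tag == "is_a") isa <- c(isa, val)
      else if (tag == "is_obsolete" && identical(tolower(val), "true")) obsolete <- TRUE
    }
    if (is.null(id)) {
      stop(sprintf("OBO [Term] stanza starting at line %d has no id", starts[k]),
           call. = FALSE)
    }
    if (obsolete) next
    ids <- c(ids, id)
    if (!is.null(nm)) labels[id] <- nm
    if (length(isa)) {
      children <- c(children, rep(id, length(isa)))
      parents <- c(parents, isa)
    }
  }
  if (length(ids) == 0L) stop("OBO file contains no non-obsolete terms", call. = FALSE)
  ontology_dag(cbind(children, parents), terms = ids, labels = labels)
}

check_terms <- function(G, x) {
  stopifnot(inherits(G, "ontology_dag"))
  missing <- setdiff(x, G$terms)
  if (length(missing)) {
    stop(sprintf("unknown term%s: %s",
                 if (length(missing) > 1L) "s" else "",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Term depth (longest root path)
#'
#' The depth of a term is the number of edges on the longest directed
#' path from any root down to the term. Roots have depth 0. On
#' multi-parent DAGs this can exceed the shortest root distance; the
#' greatest-depth convention is what the lowest-common-ancestor
#' selection uses.
#'
#' @param G an [ontology_dag()].
#' @param x term ID(s).
#' @return Integer vector of depths.
#' @export
term_depth <- function(G, x) {
  check_terms(G, x)
  unname(G$depth[x])
}

#' Shortest distance from an ancestor to a descendant
#'
#' Number of edges on the shortest directed path from `a` down to `x`.
#' Every term is its own ancestor at distance 0. It is an error to ask
#' for the distance from a non-ancestor.
#'
#' @param G an [ontology_dag()].
#' @param a ancestor term ID.
#' @param x descendant term ID.
#' @return Non-negative integer.
#' @export
ancestor_distance <- function(G, a, x) {
  check_terms(G, c(a, x))
  d <- dag_distances(G)[a, x]
  if (!is.finite(d)) {
    stop(sprintf("'%s' is not an ancestor of '%s'", a, x), call. = FALSE)
  }
  as.integer(d)
}

#' Shortest distance from a root to a term
#'
#' Minimum over the DAG's roots of the shortest directed root-to-term
#' distance. When the DAG has several roots this equals the distance from
#' an implicit virtual super-root (connected to every real root) minus
#' the virtual edge, which keeps the taxonomic distance measures well
#' defined on multi-root vocabularies.
#'
#' @param G an [ontology_dag()].
#' @param x term ID.
#' @return Non-negative integer.
#' @export
root_distance <- function(G, x) {
  check_terms(G, x)
  as.integer(min(dag_distances(G)[G$roots, x]))
}

# All ancestors of x, x included.
ancestor_set <- function(G, x) {
  G$terms[is.finite(dag_distances(G)[, x])]
}

#' Lowest common ancestor of two terms
#'
#' Returns the common ancestor of `x` and `y` of greatest depth, where
#' depth is the longest-path depth ([term_depth()]). A term counts as its
#' own ancestor, so `term_lca(G, x, x) == x`. Ties at equal depth are
#' broken by minimizing the summed shortest distances to `x` and `y`, and
#' remaining ties lexicographically by term ID, making the choice
#' deterministic and symmetric.
#'
#' @param G an [ontology_dag()].
#' @param x,y term IDs.
#' @return A term ID.
#' @export
term_lca <- function(G, x, y) {
  check_terms(G, c(x, y))
  D <- dag_distances(G)
  common <- G$terms[is.finite(D[, x]) & is.finite(D[, y])]
  if (length(common) == 0L) {
    stop(sprintf("terms '%s' and '%s' have no common ancestor", x, y),
         call. = FALSE)
  }
  dep <- G$depth[common]
  cand <- common[dep == max(dep)]
  if (length(cand) > 1L) {
    dsum <- D[cand, x] + D[cand, y]
    cand <- sort(cand[dsum == min(dsum)])
  }
  unname(cand[1L])
}
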