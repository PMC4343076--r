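#' Typed heterogeneous graphs
#'
#' A `hetero_graph` holds typed nodes and named directed relations, each
#' relation declared between a source and a target node type. It is the
#' substrate for [hetesim()], the relevance-path relatedness baseline.
#'
#' @param nodes data frame (or two-column matrix) with columns `id`,
#'   `type`.
#' @param relations named list; each element a list with components
#'   `from` (source type), `to` (target type) and `edges` (two-column
#'   character matrix of (source id, target id) pairs, possibly empty).
#' @return An object of class `hetero_graph`.
#' @seealso [relevance_path()], [hetesim()], [add_identity_relation()]
#' @export
hetero_graph <- function(nodes, relations = list()) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  names(nodes) <- c("id", "type")
  nodes$id <- as.character(nodes$id)
  nodes$type <- as.character(nodes$type)
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node IDs", call. = FALSE)
  }
  type_of <- stats::setNames(nodes$type, nodes$id)
  if (length(relations) &&
      (is.null(names(relations)) || any(!nzchar(names(relations))))) {
    stop("relations must be a named list", call. = FALSE)
  }
  rel_names <- names(relations)
  relations <- lapply(rel_names, function(rn) {
    r <- relations[[rn]]
    edges <- r$edges
    if (is.null(edges) || length(edges) == 0L) {
      edges <- matrix(character(), ncol = 2L)
    }
    edges <- unique(as.matrix(edges))
    storage.mode(edges) <- "character"
    if (nrow(edges)) {
      unknown <- setdiff(c(edges), nodes$id)
      if (length(unknown)) {
        stop(sprintf("relation '%s' references unknown node(s): %s",
                     rn, paste(unknown, collapse = ", ")), call. = FALSE)
      }
      bad_src <- type_of[edges[, 1L]] != r$from
      bad_tgt <- type_of[edges[, 2L]] != r$to
      if (any(bad_src) || any(bad_tgt)) {
        stop(sprintf("relation '%s' (%s -> %s) has edges with mismatched endpoint types",
                     rn, r$from, r$to), call. = FALSE)
      }
    }
    list(from = r$from, to = r$to, edges = edges)
  })
  names(relations) <- rel_names
  structure(
    list(nodes = nodes, type_of = type_of, relations = relations),
    class = "hetero_graph"
  )
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat(sprintf("Heterogeneous graph: %d nodes (%d types), %d relations\n",
              nrow(x$nodes), length(unique(x$nodes$type)),
              length(x$relations)))
  for (rn in names(x$relations)) {
    r <- x$relations[[rn]]
    cat(sprintf("  %s: %s -> %s (%d edges)\n", rn, r$from, r$to,
                nrow(r$edges)))
  }
  invisible(x)
}

#' Add the identity relation of a node type
#'
#' Declares a relation containing exactly the self-loops of every node
#' of the given type. The identity relation is the standard middle step
#' of the annotation meta-path (annotates, identity, annotated-by):
#' two entities' term walks must meet at the *same* term.
#'
#' @param H a [hetero_graph()].
#' @param type node type.
#' @param name relation name (default `"identity"`).
#' @return The updated `hetero_graph`.
#' @export
add_identity_relation <- function(H, type, name = "identity") {
  stopifnot(inherits(H, "hetero_graph"))
  ids <- H$nodes$id[H$nodes$type == type]
  H$relations[[name]] <- list(from = type, to = type,
                              edges = cbind(ids, ids, deparse.level = 0))
  H
}

#' Relevance paths
#'
#' An ordered sequence of relation names whose types chain: the target
#' type of each relation must equal the source type of the next. The
#' path constrains which graph walks [hetesim()] considers.
#'
#' @param H a [hetero_graph()].
#' @param relations character vector of relation names (length >= 1).
#' @return An object of class `relevance_path`.
#' @export
relevance_path <- function(H, relations) {
  stopifnot(inherits(H, "hetero_graph"))
  relations <- as.character(relations)
  if (length(relations) < 1L) {
    stop("a relevance path needs at least one relation", call. = FALSE)
  }
  unknown <- setdiff(relations, names(H$relations))
  if (length(unknown)) {
    stop(sprintf("unknown relation(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (length(relations) > 1L) {
    for (i in seq_len(length(relations) - 1L)) {
      t1 <- H$relations[[relations[i]]]$to
      t2 <- H$relations[[relations[i + 1L]]]$from
      if (t1 != t2) {
        stop(sprintf("type mismatch along path: '%s' targets %s but '%s' starts from %s",
                     relations[i], t1, relations[i + 1L], t2), call. = FALSE)
      }
    }
  }
  structure(list(relations = relations), class = "relevance_path")
}

rel_out <- function(H, rel, s) {
  e <- H$relations[[rel]]$edges
  e[e[, 1L] == s, 2L]
}

rel_in <- function(H, rel, t) {
  e <- H$relations[[rel]]$edges
  e[e[, 2L] == t, 1L]
}

#' HeteSim along a relevance path
#'
#' HeteSim measures how likely two typed nodes are to meet at the same
#' intermediate entity when the source walks forward along the relevance
#' path and the target walks backward. It is computed recursively by
#' peeling the path from both ends:
#'
#' * empty inner path: 1 if the two nodes coincide, else 0;
#' * single relation `R`: `|O(s|R) ∩ I(t|R)| / (|O(s|R)| · |I(t|R)|)` —
#'   the probability two uniform one-step walks land on the same node;
#' * longer paths: the average of the inner HeteSim over all pairs of a
#'   forward neighbor of `s` (first relation) and a backward neighbor of
#'   `t` (last relation).
#'
#' A node with no neighbors under its end relation gives 0 (a sparsely
#' connected entity is simply unrelated, not an error). Along the
#' annotation meta-path (annotates, identity, annotated-by) this reduces
#' to `|A1 ∩ A2| / (|A1| · |A2|)`, so entities with disjoint annotation
#' sets score exactly 0 — only exact term matches count, which is what
#' makes HeteSim a deliberately strict baseline for [annsim()].
#'
#' @param H a [hetero_graph()].
#' @param s,t node IDs; `s` must have the path's source type and `t` its
#'   terminal type.
#' @param P a [relevance_path()] (or character vector of relation names).
#' @return A number in `[0, 1]`.
#' @export
hetesim <- function(H, s, t, P) {
  stopifnot(inherits(H, "hetero_graph"))
  if (!inherits(P, "relevance_path")) P <- relevance_path(H, P)
  rels <- P$relations
  for (nd in c(s, t)) {
    if (!nd %in% H$nodes$id) {
      stop(sprintf("unknown node '%s'", nd), call. = FALSE)
    }
  }
  if (H$type_of[[s]] != H$relations[[rels[1L]]]$from) {
    stop(sprintf("node '%s' has type %s but the path starts from type %s",
                 s, H$type_of[[s]], H$relations[[rels[1L]]]$from),
         call. = FALSE)
  }
  l <- length(rels)
  if (H$type_of[[t]] != H$relations[[rels[l]]]$to) {
    stop(sprintf("node '%s' has type %s but the path ends at type %s",
                 t, H$type_of[[t]], H$relations[[rels[l]]]$to),
         call. = FALSE)
  }
  hetesim_rec(H, s, t, rels)
}

hetesim_rec <- function(H, s, t, rels) {
  l <- length(rels)
  if (l == 0L) return(as.numeric(s == t))
  O <- rel_out(H, rels[1L], s)
  I <- rel_in(H, rels[l], t)
  if (length(O) == 0L || length(I) == 0L) return(0)
  if (l == 1L) {
    return(length(intersect(O, I)) / (length(O) * length(I)))
  }
  inner <- if (l > 2L) rels[2:(l - 1L)] else character()
  total <- 0
  for (u in O) for (v in I) total <- total + hetesim_rec(H, u, v, inner)
  total / (length(O) * length(I))
}

#' Build the annotation meta-path graph of an annotation graph
#'
#' Convenience bridge: converts an [annotation_graph()] into a
#' [hetero_graph()] with node types `entity` and `term`, relations
#' `annotates` (entity -> term), its inverse `annotated_by`
#' (term -> entity) and the `identity` relation on terms, i.e. the
#' standard (annotates, identity, annotated_by) relevance path setup.
#'
#' @param AG an [annotation_graph()].
#' @return A `hetero_graph`.
#' @export
as_hetero_graph <- function(AG) {
  stopifnot(inherits(AG, "annotation_graph"))
  terms <- sort(unique(unlist(AG$annotations)))
  nodes <- data.frame(
    id = c(AG$entities, terms),
    type = c(rep("entity", length(AG$entities)), rep("term", length(terms))),
    stringsAsFactors = FALSE
  )
  ann_edges <- do.call(rbind, lapply(AG$entities, function(e) {
    cbind(e, AG$annotations[[e]], deparse.level = 0)
  }))
  H <- hetero_graph(nodes, list(
    annotates = list(from = "entity", to = "term", edges = ann_edges),
    annotated_by = list(from = "term", to = "entity",
                        edges = ann_edges[, 2:1, drop = FALSE])
  ))
  add_identity_relation(H, "term")
}

#' Load a heterogeneous graph from TSV
#'
#' The file interleaves two kinds of lines: type declarations
#' `@relation<TAB>name<TAB>source_type<TAB>target_type` and
#' `@node<TAB>id<TAB>type`, plus edge lines
#' `relation<TAB>source<TAB>target`. `#` comments and blank lines are
#' ignored.
#'
#' @param path path to the graph TSV.
#' @return A [hetero_graph()].
#' @export
load_hetero_graph <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("graph file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)

  nodes <- list(); rel_decl <- list(); rel_edges <- list()
  for (f in fields) {
    if (f[[1]] == "@node") {
      if (length(f) != 3L) stop("@node lines need: @node<TAB>id<TAB>type", call. = FALSE)
      nodes[[length(nodes) + 1L]] <- c(f[[2]], f[[3]])
    } else if (f[[1]] == "@relation") {
      if (length(f) != 4L) {
        stop("@relation lines need: @relation<TAB>name<TAB>source_type<TAB>target_type",
             call. = FALSE)
      }
      rel_decl[[f[[2]]]] <- list(from = f[[3]], to = f[[4]])
    } else {
      if (length(f) != 3L) {
        stop(sprintf("edge lines need: relation<TAB>source<TAB>target (got '%s')",
                     paste(f, collapse = "\\t")), call. = FALSE)
      }
      rel_edges[[f[[1]]]] <- rbind(rel_edges[[f[[1]]]],
                                   cbind(f[[2]], f[[3]], deparse.level = 0))
    }
  }
  undecl <- setdiff(names(rel_edges), names(rel_decl))
  if (length(undecl)) {
    stop(sprintf("edges reference undeclared relation(s): %s",
                 paste(undecl, collapse = ", ")), call. = FALSE)
  }
  relations <- lapply(names(rel_decl), function(rn) {
    d <- rel_decl[[rn]]
    list(from = d$from, to = d$to,
         edges = rel_edges[[rn]] %||% matrix(character(), ncol = 2L))
  })
  names(relations) <- names(rel_decl)
  hetero_graph(do.call(rbind, nodes), relations)
}
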