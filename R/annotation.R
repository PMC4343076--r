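#' Annotation graphs
#'
#' An `annotation_graph` links entities (drugs, proteins, diseases —
#' plain IDs, typed only by the caller) to non-empty sets of ontology
#' terms. It is the input to [annsim()]: the similarity of two entities
#' is computed from their two term sets on the shared ontology.
#'
#' @param annotations named list mapping entity ID to a character vector
#'   of term IDs (duplicates are collapsed).
#' @param ontology the [ontology_dag()] the terms live in.
#' @param unknown_term_policy what to do with terms absent from the
#'   ontology: `"error"` (default) aborts naming the entity and term;
#'   `"drop"` removes them with a warning, and removes (with a warning)
#'   any entity left without annotations.
#' @return An object of class `annotation_graph` with components
#'   `entities`, `annotations` (named list of character sets) and
#'   `ontology`.
#' @seealso [load_annotations()], [annsim()]
#' @export
annotation_graph <- function(annotations, ontology,
                             unknown_term_policy = c("error", "drop")) {
  unknown_term_policy <- match.arg(unknown_term_policy)
  stopifnot(inherits(ontology, "ontology_dag"))
  if (length(annotations) == 0L) {
    stop("annotation set is empty", call. = FALSE)
  }
  if (is.null(names(annotations)) || any(!nzchar(names(annotations)))) {
    stop("annotations must be a named list (entity IDs as names)", call. = FALSE)
  }
  annotations <- lapply(annotations, function(x) sort(unique(as.character(x))))

  for (e in names(annotations)) {
    bad <- setdiff(annotations[[e]], ontology$terms)
    if (length(bad)) {
      if (unknown_term_policy == "error") {
        stop(sprintf("entity '%s' is annotated with unknown term%s: %s",
                     e, if (length(bad) > 1L) "s" else "",
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
      warning(sprintf("dropping %d unknown term%s from entity '%s'",
                      length(bad), if (length(bad) > 1L) "s" else "", e),
              call. = FALSE)
      annotations[[e]] <- setdiff(annotations[[e]], bad)
    }
  }
  empty <- names(annotations)[lengths(annotations) == 0L]
  if (length(empty)) {
    if (unknown_term_policy == "error") {
      stop(sprintf("entities without annotations: %s",
                   paste(empty, collapse = ", ")), call. = FALSE)
    }
    warning(sprintf("removing entit%s with no remaining annotations: %s",
                    if (length(empty) > 1L) "ies" else "y",
                    paste(empty, collapse = ", ")), call. = FALSE)
    annotations <- annotations[lengths(annotations) > 0L]
  }
  if (length(annotations) == 0L) {
    stop("no entities remain after applying the unknown-term policy",
         call. = FALSE)
  }
  structure(
    list(entities = names(annotations), annotations = annotations,
         ontology = ontology),
    class = "annotation_graph"
  )
}

#' @export
print.annotation_graph <- function(x, ...) {
  sizes <- lengths(x$annotations)
  cat(sprintf("Annotation graph: %d entities over %d ontology terms\n",
              length(x$entities), length(x$ontology$terms)))
  cat(sprintf("  annotation set sizes: min %d, median %g, max %d\n",
              min(sizes), stats::median(sizes), max(sizes)))
  invisible(x)
}

#' Load entity annotations from a TSV file
#'
#' Reads a two-column `entity_id<TAB>term_id` file (`#` comments
#' allowed), deduplicates per-entity term sets and validates every term
#' against the ontology under the chosen policy.
#'
#' @param path path to the annotation TSV.
#' @param ontology an [ontology_dag()].
#' @inheritParams annotation_graph
#' @return An [annotation_graph()].
#' @export
load_annotations <- function(path, ontology,
                             unknown_term_policy = c("error", "drop")) {
  m <- read_tsv_pairs(path, what = "annotation file")
  if (nrow(m) == 0L) stop("annotation file is empty", call. = FALSE)
  if (any(is.na(m[, 2L]))) {
    stop("annotation file rows must have two columns (entity_id, term_id)",
         call. = FALSE)
  }
  annotation_graph(split(m[, 2L], m[, 1L]), ontology,
                   unknown_term_policy = unknown_term_policy)
}

#' Write an annotation graph to TSV
#'
#' Inverse of [load_annotations()]: one `entity_id<TAB>term_id` row per
#' annotation, entities and terms in sorted order.
#'
#' @param AG an [annotation_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(AG, path) {
  stopifnot(inherits(AG, "annotation_graph"))
  rows <- unlist(lapply(sort(AG$entities), function(e) {
    paste(e, AG$annotations[[e]], sep = "\t")
  }))
  writeLines(rows, path)
  invisible(path)
}

#' Annotations of one entity
#'
#' @param AG an [annotation_graph()].
#' @param entity entity ID.
#' @return Character vector of term IDs (sorted).
#' @export
entity_annotations <- function(AG, entity) {
  stopifnot(inherits(AG, "annotation_graph"))
  if (!entity %in% AG$entities) {
    stop(sprintf("unknown entity '%s'", entity), call. = FALSE)
  }
  AG$annotations[[entity]]
}

#' Number of distinct annotations of an entity
#'
#' @inheritParams entity_annotations
#' @return Positive integer.
#' @export
annotation_count <- function(AG, entity) {
  length(entity_annotations(AG, entity))
}
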