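#' AnnSim: Dice-normalized optimal annotation matching
#'
#' AnnSim scores two annotated entities by how well their annotation
#' sets can be aligned on the ontology. With annotation sets `A1`, `A2`
#' and an exact 1-1 maximum-weight bipartite matching `M` over the
#' complete similarity graph between them,
#'
#' \deqn{AnnSim(c_1, c_2) = \frac{2 \sum_{(a_1,a_2) \in M} sim(a_1, a_2)}
#'       {|A_1| + |A_2|}}
#'
#' in the style of the Dice coefficient. The score is symmetric, lies in
#' `[0, 1]`, reaches 1 exactly when the sets have equal cardinality and
#' every matched edge weight is 1, and penalizes cardinality differences
#' through the bound `AnnSim <= 2 min(|A1|,|A2|) / (|A1|+|A2|)`: terms on
#' the larger side left unmatched contribute nothing to the numerator
#' but still count in the denominator.
#'
#' @param c1,c2 entity IDs present in `AG`.
#' @param AG an [annotation_graph()].
#' @param measure taxonomic edge-weight measure, `"tax"` or `"ps"`.
#' @return A number in `[0, 1]`.
#' @examples
#' fix <- worked_fixtures()
#' ag <- fix$chain$annotations
#' annsim("ex", "ey", ag)           # matching on the chain ontology
#' annsim("ex", "ex", ag)           # identical entity: 1
#' @export
annsim <- function(c1, c2, AG, measure = c("tax", "ps")) {
  measure <- match.arg(measure)
  A1 <- entity_annotations(AG, c1)
  A2 <- entity_annotations(AG, c2)
  annsim_sets(A1, A2, AG$ontology, measure)
}

# Score two raw term sets; tolerates one empty side (score 0).
annsim_sets <- function(A1, A2, G, measure) {
  n1 <- length(unique(A1)); n2 <- length(unique(A2))
  if (n1 + n2 == 0L) stop("both annotation sets are empty", call. = FALSE)
  if (n1 == 0L || n2 == 0L) return(0)
  BG <- build_bipartite(A1, A2, G, measure)
  M <- max_weight_matching(BG)
  annsim_score(M, n1, n2)
}

#' AnnSim score from a solved matching
#'
#' The Dice-style normalization step: `2 * total_weight / (n1 + n2)`.
#'
#' @param M an [max_weight_matching()] result (or any list with a
#'   `total_weight` component).
#' @param n1,n2 the two annotation-set cardinalities.
#' @return A number in `[0, 1]` when weights are in `[0, 1]`.
#' @export
annsim_score <- function(M, n1, n2) {
  if (n1 + n2 == 0) stop("n1 + n2 must be positive", call. = FALSE)
  2 * M$total_weight / (n1 + n2)
}

#' All-pairs AnnSim matrix
#'
#' Computes the symmetric AnnSim matrix over a set of entities, sharing
#' one term-similarity table across all pairs. Per-entity summaries
#' (mean and standard deviation of the similarities to the *other*
#' entities) are attached as the `"summary"` attribute — the usual way
#' such pairwise tables are reported.
#'
#' @param AG an [annotation_graph()].
#' @param entities entity IDs (default: all entities in `AG`).
#' @param measure taxonomic edge-weight measure, `"tax"` or `"ps"`.
#' @return A symmetric numeric matrix with entity dimnames; attribute
#'   `"summary"` is a data frame with columns `entity`, `mean`, `sd`
#'   (sample standard deviation over the off-diagonal row entries).
#' @export
pairwise_annsim <- function(AG, entities = AG$entities,
                            measure = c("tax", "ps")) {
  measure <- match.arg(measure)
  stopifnot(inherits(AG, "annotation_graph"))
  missing <- setdiff(entities, AG$entities)
  if (length(missing)) {
    stop(sprintf("unknown entities: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  sets <- AG$annotations[entities]
  all_terms <- sort(unique(unlist(sets)))
  S <- term_similarity_matrix(AG$ontology, all_terms, measure)

  k <- length(entities)
  out <- matrix(0, k, k, dimnames = list(entities, entities))
  for (i in seq_len(k)) {
    Ai <- sets[[i]]
    out[i, i] <- {
      M <- max_weight_matching(S[Ai, Ai, drop = FALSE])
      annsim_score(M, length(Ai), length(Ai))
    }
    if (i == k) break
    for (j in (i + 1L):k) {
      Aj <- sets[[j]]
      M <- max_weight_matching(S[Ai, Aj, drop = FALSE])
      out[i, j] <- out[j, i] <- annsim_score(M, length(Ai), length(Aj))
    }
  }
  if (k > 1L) {
    means <- vapply(seq_len(k), function(i) mean(out[i, -i]), numeric(1))
    sds <- vapply(seq_len(k), function(i) stats::sd(out[i, -i]), numeric(1))
  } else {
    means <- NA_real_; sds <- NA_real_
  }
  attr(out, "summary") <- data.frame(entity = entities, mean = means,
                                     sd = sds, row.names = NULL)
  out
}
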