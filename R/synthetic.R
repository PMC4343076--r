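#' Configuration for the synthetic generators
#'
#' Bundles every knob of the seeded generators: ontology shape, number
#' of entities and annotation-set sizes, category structure, and the
#' focus-subtree mixing used to plant entity families with high mutual
#' AnnSim. Defaults are desk-scale: a few hundred terms and a few dozen
#' entities, annotation counts spanning the wide range seen in real
#' drug-annotation data (from a single term to on the order of a
#' hundred), multi-parent terms allowed.
#'
#' @param seed integer RNG seed; every generator output is a pure
#'   function of its config.
#' @param n_terms total number of ontology terms (>= 2).
#' @param max_parents maximum parents per non-root term (>= 1; 1 gives a
#'   tree).
#' @param target_depth number of levels below the root.
#' @param n_entities number of annotated entities.
#' @param annotation_size_range integer (min, max) annotation-set sizes.
#' @param n_categories number of distinct category labels.
#' @param category_sets_per_entity integer (min, max) categories per
#'   entity.
#' @param n_families number of entity families for subtree-biased
#'   annotation sampling.
#' @param subtree_bias probability in `[0, 1]` that an annotation is
#'   drawn from the entity's family subtree rather than uniformly (0
#'   disables the family structure; 1 samples purely from the subtree).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_terms = 200L, max_parents = 3L,
                             target_depth = 8L, n_entities = 30L,
                             annotation_size_range = c(1L, 25L),
                             n_categories = 10L,
                             category_sets_per_entity = c(1L, 3L),
                             n_families = 1L, subtree_bias = 0) {
  cfg <- list(seed = as.integer(seed), n_terms = as.integer(n_terms),
              max_parents = as.integer(max_parents),
              target_depth = as.integer(target_depth),
              n_entities = as.integer(n_entities),
              annotation_size_range = as.integer(annotation_size_range),
              n_categories = as.integer(n_categories),
              category_sets_per_entity = as.integer(category_sets_per_entity),
              n_families = as.integer(n_families),
              subtree_bias = as.numeric(subtree_bias))
  counts <- c(cfg$n_terms, cfg$max_parents, cfg$target_depth,
              cfg$n_entities, cfg$n_categories, cfg$n_families)
  if (any(counts < 1L)) stop("all counts must be positive", call. = FALSE)
  if (cfg$n_terms < 2L) stop("n_terms must be at least 2", call. = FALSE)
  for (rng in list(cfg$annotation_size_range, cfg$category_sets_per_entity)) {
    if (length(rng) != 2L || rng[1L] > rng[2L] || rng[1L] < 1L) {
      stop("ranges must be (min, max) with 1 <= min <= max", call. = FALSE)
    }
  }
  if (cfg$subtree_bias < 0 || cfg$subtree_bias > 1) {
    stop("subtree_bias must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

#' Generate a random rooted ontology DAG
#'
#' Terms are laid out on levels 1..`target_depth` below a single root;
#' each term receives one parent from the level directly above (which
#' fixes its longest-path depth and guarantees reachability from the
#' root) plus up to `max_parents - 1` extra parents from any strictly
#' shallower level, yielding multi-parent diamonds when
#' `max_parents > 1`. Deterministic for a given config.
#'
#' @param cfg a [generator_config()].
#' @return An [ontology_dag()] with terms `root`, `t001`, `t002`, ...
#' @export
gen_ontology <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_terms
    ids <- c("root", sprintf("t%03d", seq_len(n - 1L)))
    depth_levels <- min(cfg$target_depth, n - 1L)
    # every level 1..depth_levels holds at least one term (pinned in
    # index order); the remaining terms land on random levels
    lev <- integer(n); lev[1L] <- 0L
    lev[1L + seq_len(depth_levels)] <- seq_len(depth_levels)
    if (n - 1L > depth_levels) {
      lev[(depth_levels + 2L):n] <-
        resample(seq_len(depth_levels), n - 1L - depth_levels, replace = TRUE)
    }
    children <- character(); parents <- character()
    for (i in 2:n) {
      above <- which(lev == lev[i] - 1L)
      shallower <- which(lev < lev[i])
      main <- resample(above, 1L)
      extra_n <- sample.int(cfg$max_parents, 1L) - 1L
      pool <- setdiff(shallower, main)
      extra <- if (extra_n > 0L && length(pool) > 0L) {
        resample(pool, min(extra_n, length(pool)))
      } else integer()
      ps <- c(main, extra)
      children <- c(children, rep(ids[i], length(ps)))
      parents <- c(parents, ids[ps])
    }
    ontology_dag(cbind(children, parents))
  })
}

#' Generate a random annotation graph on an ontology
#'
#' Each entity draws a uniform set size from `annotation_size_range` and
#' samples that many distinct terms. With `subtree_bias > 0`, entities
#' are split round-robin into `n_families`; each family owns a focus
#' subtree (the descendants of a randomly chosen internal term), and
#' each annotation is drawn from the family subtree with probability
#' `subtree_bias`, uniformly otherwise. Families therefore share
#' topically close terms, which is what gives within-family pairs
#' higher AnnSim than cross-family pairs.
#'
#' @param G an [ontology_dag()].
#' @param cfg a [generator_config()].
#' @return An [annotation_graph()] with entities `e01`, `e02`, ...;
#'   attribute `"family"` maps entity to family index when
#'   `subtree_bias > 0`.
#' @export
gen_annotations <- function(G, cfg) {
  stopifnot(inherits(G, "ontology_dag"), inherits(cfg, "generator_config"))
  pool <- setdiff(G$terms, G$roots)
  if (cfg$annotation_size_range[2L] > length(pool)) {
    stop("annotation_size_range exceeds the number of non-root terms",
         call. = FALSE)
  }
  with_seed(cfg$seed + 1L, {
    fam_of <- rep_len(seq_len(cfg$n_families), cfg$n_entities)
    subtrees <- NULL
    if (cfg$subtree_bias > 0) {
      D <- dag_distances(G)
      need <- cfg$annotation_size_range[2L]
      # candidate subtree anchors: internal terms with enough descendants
      desc_count <- rowSums(is.finite(D)) - 1L
      anchors <- G$terms[desc_count >= need & !(G$terms %in% G$roots)]
      if (length(anchors) < cfg$n_families) {
        stop("ontology too shallow for the requested family subtrees",
             call. = FALSE)
      }
      picked <- resample(anchors, cfg$n_families)
      subtrees <- lapply(picked, function(a) {
        setdiff(G$terms[is.finite(D[a, ])], G$roots)
      })
    }
    sizes <- resample(seq(cfg$annotation_size_range[1L],
                          cfg$annotation_size_range[2L]),
                      cfg$n_entities, replace = TRUE)
    ann <- lapply(seq_len(cfg$n_entities), function(i) {
      k <- sizes[i]
      if (is.null(subtrees)) return(resample(pool, k))
      fam_pool <- subtrees[[fam_of[i]]]
      from_fam <- stats::rbinom(1L, k, cfg$subtree_bias)
      from_fam <- min(from_fam, length(fam_pool))
      fam_part <- resample(fam_pool, from_fam)
      rest_pool <- setdiff(pool, fam_part)
      c(fam_part, resample(rest_pool, k - from_fam))
    })
    names(ann) <- sprintf("e%02d", seq_len(cfg$n_entities))
    AG <- annotation_graph(ann, G)
    attr(AG, "family") <- stats::setNames(fam_of, names(ann))
    AG
  })
}

#' Generate random category sets for entities
#'
#' Each entity draws a uniform number of categories from
#' `category_sets_per_entity` out of `cat01`..`catN`, without
#' replacement.
#'
#' @param cfg a [generator_config()].
#' @param entities entity IDs (default `e01..`, `n_entities` of them).
#' @return Named list of category sets.
#' @export
gen_categories <- function(cfg, entities = sprintf("e%02d", seq_len(cfg$n_entities))) {
  stopifnot(inherits(cfg, "generator_config"))
  labs <- sprintf("cat%02d", seq_len(cfg$n_categories))
  rng <- cfg$category_sets_per_entity
  if (rng[2L] > length(labs)) {
    stop("category_sets_per_entity exceeds n_categories", call. = FALSE)
  }
  with_seed(cfg$seed + 2L, {
    out <- lapply(seq_along(entities), function(i) {
      k <- resample(seq(rng[1L], rng[2L]), 1L)
      sort(resample(labs, k))
    })
    stats::setNames(out, entities)
  })
}

#' Group entities by identical category sets
#'
#' The gold-standard clustering construction: two entities share a
#' cluster exactly when their category sets are identical. Its average
#' category-based score is 1 by construction.
#'
#' @param categories named list of category sets.
#' @return Named character vector mapping entity to cluster label.
#' @export
cluster_by_identical_categories <- function(categories) {
  keys <- vapply(categories, function(s) paste(sort(unique(s)), collapse = "|"),
                 character(1))
  labs <- stats::setNames(sprintf("c%02d", seq_along(unique(keys))), unique(keys))
  stats::setNames(unname(labs[keys]), names(categories))
}

#' Fixed worked-example fixtures
#'
#' Small hand-built inputs on which the package's measures take
#' round-number values, used throughout the tests and the acceptance
#' checks:
#'
#' * `chain`: ontology `root->v1->v2->L`, `L->x1->x`, `L->y1->y` — the
#'   LCA of `x` and `y` sits 3 edges below the root and 2 above each
#'   term, so `1 - d_tax(x, y) = 0.60` and `1 - d_ps(x, y) = 3/7`
#'   (0.43 at two decimals). Includes a two-entity annotation graph
#'   (`ex` = \{x\}, `ey` = \{y\}).
#' * `shortcut_dag`: `root->a->b->L`, `L->x`, `L->y` plus the shortcut
#'   `b->y`, making the shortest root distances 4 and 3 while the LCA
#'   `L` stays 1 edge above each term: `1 - d_tax(x, y) = 5/7` (0.714).
#' * `disjoint_annotations`: heterogeneous graph with entity `s`
#'   annotated by 3 terms and entity `t` by 7 disjoint terms, plus the
#'   (annotates, identity, annotated_by) path — HeteSim is exactly 0.
#' * `gold_clustering`: 20 entities with category sets drawn so that
#'   several entities share identical sets; clustering them by identical
#'   sets gives at least one multi-member cluster, many singletons, and
#'   an average category-based score of exactly 1.
#'
#' @return Named list of fixtures; see Details for each component's
#'   structure.
#' @examples
#' fix <- worked_fixtures()
#' term_similarity(fix$chain$ontology, "x", "y", "tax")
#' @export
worked_fixtures <- function() {
  chain_g <- ontology_dag(cbind(
    c("v1", "v2", "L", "x1", "x", "y1", "y"),
    c("root", "v1", "v2", "L", "x1", "L", "y1")
  ))
  chain_ag <- annotation_graph(list(ex = "x", ey = "y"), chain_g)

  shortcut_g <- ontology_dag(cbind(
    c("a", "b", "L", "x", "y", "y"),
    c("root", "a", "b", "L", "L", "b")
  ))

  s_terms <- sprintf("s%d", 1:3)
  t_terms <- sprintf("u%d", 1:7)
  het_nodes <- data.frame(
    id = c("s", "t", s_terms, t_terms),
    type = c("entity", "entity", rep("term", 10L)),
    stringsAsFactors = FALSE
  )
  ann_edges <- rbind(cbind("s", s_terms), cbind("t", t_terms))
  H <- hetero_graph(het_nodes, list(
    annotates = list(from = "entity", to = "term", edges = ann_edges),
    annotated_by = list(from = "term", to = "entity",
                        edges = ann_edges[, 2:1])
  ))
  H <- add_identity_relation(H, "term")

  gold_entities <- sprintf("e%02d", 1:20)
  gold_cats <- with_seed(20260101L, {
    base_sets <- list(c("catA", "catB"), c("catA", "catC"), "catB",
                      c("catB", "catC", "catD"))
    out <- vector("list", 20L)
    # first eight entities reuse four base sets pairwise -> 4 clusters of 2
    for (i in 1:8) out[[i]] <- base_sets[[((i - 1L) %% 4L) + 1L]]
    # remaining twelve get distinct singleton-ish sets -> singletons
    for (i in 9:20) out[[i]] <- paste0("solo", i)
    stats::setNames(out, gold_entities)
  })
  gold_clu <- cluster_by_identical_categories(gold_cats)

  list(
    chain = list(ontology = chain_g, pair = c("x", "y"),
                 annotations = chain_ag),
    shortcut_dag = list(ontology = shortcut_g, pair = c("x", "y")),
    disjoint_annotations = list(
      graph = H, s = "s", t = "t",
      path = c("annotates", "identity", "annotated_by")
    ),
    gold_clustering = list(categories = gold_cats, clustering = gold_clu)
  )
}

#' Write synthetic inputs to a directory
#'
#' Materializes one seeded scenario as the plain-text files the loaders
#' read: `ontology.tsv` (child/parent edge list), `annotations.tsv`,
#' `categories.tsv` and `clustering.tsv` (entities clustered by
#' identical category sets).
#'
#' @param cfg a [generator_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_synthetic_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "generator_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  G <- gen_ontology(cfg)
  AG <- gen_annotations(G, cfg)
  cats <- gen_categories(cfg)
  clu <- cluster_by_identical_categories(cats)

  paths <- c(ontology = file.path(dir, "ontology.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             categories = file.path(dir, "categories.tsv"),
             clustering = file.path(dir, "clustering.tsv"))
  writeLines(paste(G$edges[, 1L], G$edges[, 2L], sep = "\t"),
             paths[["ontology"]])
  write_annotations(AG, paths[["annotations"]])
  writeLines(unlist(lapply(names(cats), function(e) {
    paste(e, cats[[e]], sep = "\t")
  })), paths[["categories"]])
  writeLines(paste(names(clu), clu, sep = "\t"), paths[["clustering"]])
  invisible(paths)
}
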