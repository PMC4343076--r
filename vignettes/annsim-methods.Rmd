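---
title: "Annotation matching similarity: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation matching similarity: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annsim)
```

## The model

`annsim` treats "how similar are two annotated entities" as an optimal
transport problem at unit granularity. An entity $c$ is a set of
ontology terms $A_c$; the similarity of two entities is the best
achievable total similarity of a one-to-one pairing of their terms,
normalized so that cardinality mismatch costs:

$$\mathrm{AnnSim}(c_1,c_2)=\frac{2\,W^\ast}{|A_1|+|A_2|},\qquad
W^\ast=\max_{M\ \text{1–1}}\ \sum_{(a_1,a_2)\in M} sim(a_1,a_2).$$

The denominator is the Dice denominator: with weights bounded by 1 and
at most $\min(|A_1|,|A_2|)$ matched pairs,
$\mathrm{AnnSim}\le 2\min(|A_1|,|A_2|)/(|A_1|+|A_2|)$, and the maximum 1
is attained iff the cardinalities agree and every matched weight is 1.
Terms on the larger side that stay unmatched contribute nothing to the
numerator but still count below — this is deliberate, not an edge case:
a drug annotated with 100 conditions is *not* interchangeable with one
annotated with 3 of them.

The matching is solved exactly. The graph is bipartite, so a
rectangular assignment solver (shortest augmenting paths with dual
potentials, $O(n^2 m)$ after orienting the smaller side as rows)
suffices; general non-bipartite matching machinery would buy nothing.
Optimality of the *total weight* is the contract; when several pairings
tie, any one of them may be reported (sides are kept in sorted term
order so reported pairs are reproducible).

### Term-level weights

Edge weights are taxonomic similarities $1-d$ on the ontology DAG.
Both distances are built from three ingredients: shortest directed
distances $d(a,x)$ from an ancestor down to a term, shortest root
distances, and a lowest common ancestor chosen by *longest-path depth*.

* $d_{tax}$ compares the climb to the LCA with the two terms' overall
  specificity: siblings deep in the ontology are much closer than
  siblings under the root.
* $d_{ps}$ looks only at the LCA's own depth relative to the spread
  below it: it is small when the meeting point is specific.

Two degenerate $0/0$ cases are pinned down: $d_{tax}(r,r)=0$ for a root
$r$ (self-distance must vanish for self-similarity 1) and
$d_{ps}(r,r)=1$ (the root is the most general term there is).

### Depth versus distance on multi-parent DAGs

Depth is the *longest* root path (the conventional definition for LCA
selection); every $d(\cdot,\cdot)$ in the formulas is a *shortest*
path. On trees the two conventions agree everywhere. On multi-parent
DAGs they interact in a way that has two consequences worth knowing:

1. **Truncation of $d_{tax}$.** The greatest-depth LCA can lie farther
   (by shortest path) from a term than that term's shortest root
   distance — a term can have a shallow "shortcut" ancestor line that
   bypasses the deep meeting point. The raw ratio then exceeds 1. The
   package truncates $d_{tax}$ at 1 (similarity floored at 0), which
   the property suite exercises on random multi-parent DAGs. The
   truncation never engages on trees.
2. **No triangle inequality.** $d_{tax}$ is often described as a
   metric on taxonomies. Empirically that survives on trees (zero
   violations across the random-tree property tests) but *fails* on
   random multi-parent DAGs under any deterministic deepest-LCA
   tie-break: the test suite asserts the inequality only on trees, and
   users should not rely on it for DAG vocabularies.

LCA ties (several common ancestors at the same maximal depth) are
broken by the smallest $d(a,x)+d(a,y)$, then lexicographically by term
ID — deterministic, symmetric in $(x,y)$, and biased toward the
ancestor that makes the pair look most related.

Multi-root vocabularies are handled by an implicit virtual super-root:
the root distance of a term is the minimum over real roots, which is
the virtual-root distance minus the virtual edge. The LCA requirement
of a common ancestor still applies; two terms in disconnected
components are an error, not a 0.

## HeteSim as the strict baseline

HeteSim is included because it is the natural comparison point: a
typed-graph measure that can relate nodes of different types (drug to
drug through their disease terms) but only credits *exact* meetings.
The implementation follows the two-end peeling recursion: an empty
inner path is an indicator $[s=t]$; a single relation gives
$|O(s|R)\cap I(t|R)|/(|O(s|R)|\,|I(t|R)|)$; longer paths average the
inner value over all (forward neighbor, backward neighbor) pairs.
Empty neighbor sets yield 0 rather than an error — a sparsely annotated
entity is unrelated to everything, which is the measure's documented
behavior, not a failure.

Along the annotation meta-path `(annotates, identity, annotated_by)`
the recursion collapses to the closed form
$|A_1\cap A_2|/(|A_1|\,|A_2|)$. That closed form settles a property one
might guess wrongly: *adding a shared annotation to both entities can
decrease the value* (identical two-term sets score $2/4=0.5$; adding a
shared third term gives $3/9\approx0.33$). The monotonicity that does
hold — and that the tests assert — is in the overlap at fixed set
sizes. The independent test oracle computes the same quantity a
different way: it enumerates uniform random walks from both ends
(forward for the source, backward for the target) and sums the meeting
probability mass, with no recursion over the relation list.

The middle relation is taken as `identity` on the term type (exact
match at the meeting point); a real term–term edge relation is equally
expressible in the graph container for users who want walks through the
ontology itself. Cosine-normalized HeteSim variants are out of scope.

## Evaluation statistics

All statistics the package ships are the ones used to judge similarity
measures against external ground truth:

* **nDCG** with the classic form: gain is the raw relevance grade
  (panel scores on a 1–4 scale are linear, so linear gain is the
  default; exponential gain `2^rel - 1` sits behind a flag), position 1
  undiscounted, `log2(i)` discount after. Score ties are ordered by
  item ID so the statistic is a function of the data, not of sort
  stability.
* **Correlations** via `stats::cor` — Spearman uses mid-ranks, which
  matters because pairwise similarity tables repeat values heavily.
  The **Fisher z-test** compares an observed correlation against a
  reference value: $z=(\mathrm{atanh}\,r_{obs}-\mathrm{atanh}\,r_{ref})\sqrt{n-3}$,
  two-sided normal p.
* **Category-based score**: pooled mean Jaccard index of category sets
  over within-cluster pairs. Singleton clusters contribute no pairs;
  under that convention (and only under it) a gold-standard clustering
  that groups entities by identical category sets scores exactly 1 even
  when most clusters are singletons.
* **Pair-counting Jaccard agreement** between partitions,
  $n_{11}/(n_{11}+n_{10}+n_{01})$, with the vacuous all-singleton case
  defined as 1 (the co-membership relations are identical).
* **Davies–Bouldin** in two variants that differ in the separation
  term $d_{ij}$: `centroid_scatter` (default) takes the mean distance
  of cluster $i$'s points to centroid $j$ — the form stated with the
  measure as this package's users encounter it — while `standard` is
  the textbook centroid-to-centroid distance. Both share
  $d_i$ = mean distance of cluster $i$'s points to their own centroid
  and $DB=\frac1k\sum_i\max_{j\ne i}(d_i+d_j)/d_{ij}$. Coincident
  centroids (zero $d_{ij}$) are an error naming the degenerate pair.
* **Coupling**: mean pairwise cosine similarity of cluster centroids.

Clustering algorithms themselves are out of scope — the package
consumes partitions, it does not produce them.

## Synthetic data: what it emulates and what it does not

Real evaluations of this kind run on vocabularies with $10^4$–$10^5$
terms and annotation sets of size 1 to beyond 100. The generators
emulate the *shape* of that data at desk scale, not its size: default
configs use a few hundred terms, ≤ 50 entities, annotation counts
spanning 1–25 (configurable up to the wide 1–100+ regime). Problem
sizes in the test suite follow the same philosophy — random DAGs of
≤ 25 nodes where brute-force path enumeration is the oracle, 200
random assignment instances with the short side ≤ 7 where exhaustive
enumeration over injections is feasible, 20 seeded replicates for the
family-separation experiment.

`gen_ontology` lays terms on levels below a single root; each term
takes one parent from the level directly above (pinning its
longest-path depth and guaranteeing rootedness) plus optional extra
parents from shallower levels (diamonds appear whenever
`max_parents > 1`). `gen_annotations` optionally plants entity
*families*: each family owns a focus subtree, and annotations are
drawn from it with probability `subtree_bias`. With full bias,
within-family pairs share topically close (though rarely identical)
terms — the regime in which AnnSim separates families while exact-match
HeteSim stays near zero, which the acceptance suite checks across 20
seeded replicates (expecting at least 18 separations, since a random
subtree pair can occasionally overlap).

What the synthetic data does **not** emulate: real term-ID syntax,
real annotation count distributions (clinical-trial annotations are
heavy-tailed; the generator's sizes are uniform in a range),
polyhierarchy densities of specific vocabularies, and annotation noise
(wrong or obsolete terms). Passing tests therefore demonstrate
algorithmic correctness and the qualitative family-separation effect,
not performance claims about any particular real vocabulary.

Every generator is a pure function of its `generator_config` (seed
included); nothing depends on the session's global RNG state, which is
saved and restored around each call.

## Numerical conventions

* All internal values are double precision, full accuracy; rounding
  (half away from zero, `round_to()`) happens only at reporting.
* Matching weights are compared with absolute tolerance $10^{-9}$ in
  tests; the solver itself is exact up to floating-point addition.
* Distances are integer edge counts throughout; no edge weights on the
  ontology are supported or planned.
* Empty annotation sets: one empty side scores 0 (forced by the
  formula); both sides empty is an error. The `annotation_graph`
  container refuses entities with no valid annotations, so these cases
  arise only with raw term sets.
* Unknown terms in annotation files default to a hard error naming the
  entity and term; the `drop` policy exists because real extractions do
  contain terms missing from a given ontology release, but silence is
  opt-in, never the default.

## Known limitations

* One-to-one matching only; many-to-many alignment of annotation sets
  is a different (and harder) normalization problem and is not
  provided.
* Only `is_a` generalization is read from OBO input; `part_of` and
  other relations are ignored by design, so measures on vocabularies
  whose structure lives in other relations will under-estimate
  relatedness.
* The pure-R assignment solver is comfortable at desk scale
  (annotation sets into the low hundreds); aligning thousands of terms
  per entity would call for a compiled solver.
* Information-content-based term similarities (Resnik, Lin,
  Jiang–Conrath and friends) are intentionally absent; the bipartite
  machinery would accept them as weights, but corpus frequencies are
  outside the package's scope.
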