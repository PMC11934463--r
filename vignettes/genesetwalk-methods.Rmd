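---
title: "Methods: embedding gene-set collections for latent term associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: embedding gene-set collections for latent term associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Curated gene-set collections (MSigDB-style GMT files) describe thousands of
biological *terms* — pathways, functions, phenotypes, expression signatures —
each as a set of gene symbols. Direct set overlap (Jaccard index, hypergeometric
tests) finds term pairs that share genes, but it is blind to *indirect*
relationships: two terms that share few genes may still be tightly coupled
through intermediate terms and genes in the collection's connectivity
structure. `genesetwalk` makes that connectivity explicit. It builds the
bipartite gene–term incidence graph, embeds every node into a low-dimensional
vector space with biased random walks and skip-gram training, and then scores
term pairs jointly by set overlap *and* embedding distance. Pairs that are
close in embedding space despite low overlap are the interesting output: they
are candidates for latent biological associations.

## The model

### Graph

Genes $G = \{g_1,\dots,g_m\}$ and terms $T = \{t_1,\dots,t_n\}$ form a
bipartite graph with one edge per (gene, term) incidence. Genes are indexed
$0,\dots,m-1$ in first-appearance order and terms $m,\dots,m+n-1$ in
collection order, so $|V| = m + n$ and runs are reproducible; the ordering is
a package convention, not a modelling choice. Genes that appear in no term
are excluded — they would be isolated nodes with undefined walk behaviour —
and terms with empty gene sets are rejected at load time for the same reason.

### Biased second-order walks

A walk at node $c$ that arrived from node $v$ chooses the next node $x$ among
the neighbours of $c$ with unnormalized weight

$$
w(x) = \begin{cases}
1/p & d(v,x) = 0 \quad (x = v,\ \text{return})\\
1 & d(v,x) = 1 \\
1/q & d(v,x) = 2
\end{cases}
$$

where $d$ is the shortest-path distance; weights are normalized over the
neighbours of $c$. Small $q$ pushes the walk outward (depth-first flavour),
large $q$ keeps it local (breadth-first). On a bipartite graph the middle
case is unreachable for $x \ne v$ — $v$ and $x$ are in the same partition, so
$d(v,x)$ is even — which the test suite checks exhaustively against a
shortest-path oracle. The first step of each walk has no predecessor and is
uniform over the start node's neighbours. Each pass over the node set visits
the nodes in a freshly shuffled order, and exactly `walks_per_node` walks
start from every node.

### Skip-gram with negative sampling

Walks are treated as sentences. For each centre node and each context node
within `context_size` positions, the trainer performs a logistic update
against `negative_samples` noise nodes drawn from the corpus unigram
distribution raised to the $3/4$ power — the de-facto skip-gram standard.
Optimisation is plain SGD with a linearly decaying learning rate (initial
0.025, floor at $10^{-4}$ of that); the context-vector matrix starts at zero
and the centre vectors, initialised uniformly in $[-0.5/d, 0.5/d]$, are the
embedding that is returned. Arithmetic is single precision with a tabulated
sigmoid, the convention of the original word2vec implementations. All
randomness flows from one integer seed through a dedicated Mersenne Twister,
so a fixed seed reproduces the embedding bit for bit regardless of R's RNG
state.

### Pair statistics

For every unordered term pair the pair table records:

* **Jaccard index** $J(A,B) = |A \cap B| / |A \cup B|$ of the gene sets;
* **hypergeometric upper-tail p-value** $P(X \ge k)$ of observing at least
  the overlap $k$ when the two set sizes are drawn from a universe of $N$
  genes. The default universe is the number of distinct genes in the loaded
  collection; an explicit $N$ can be supplied when the collection is a
  subset of a larger annotation space. The screen is applied at raw
  $p < 0.05$; a Benjamini–Hochberg column is available but off by default,
  matching the screening (not confirmatory) role of the test;
* **embedding distance**, euclidean by default with cosine selectable. The
  published analyses never name their metric; euclidean is the natural
  companion of k-means and of the minimum spanning tree, so it is the
  default and the choice is surfaced as a parameter rather than buried;
* **normalized distance**: min–max over all pairs of the run, mapping onto
  $[0,1]$ as the reported distance axes do. Normalization is global over the
  run's pairs (not per subset), and a constant vector maps to zeros.

The "closest fraction" screen takes the value at the
$\lceil f N \rceil$-th position of the ascending distance sort ($f = 0.05$
by default) as a threshold; pairs at or below it are selected, ties
included.

### Hyperparameter selection

The search grid is the full Cartesian product of dimensions $\{32, 64\}$,
walk length $\{10,20,30\}$, $p, q \in \{0.25,0.5,1,2,4\}$, context size
$\{10,20\}$, negative samples $\{1,5,10\}$ and walks per node
$\{10,20,30\}$ — 2700 configurations, 40 epochs each. Executing the whole
grid is a cluster-scale job and is deliberately *not* a test; `evaluate_grid`
accepts any subset. Configurations are ranked by the silhouette of a seeded
k-means clustering of the term vectors (higher better) with Davies–Bouldin
as tiebreak (lower better):

$$S = \frac{1}{n}\sum_i \frac{b_i - a_i}{\max(a_i, b_i)}, \qquad
DB = \frac{1}{k}\sum_i \max_{j \ne i} \frac{\sigma_i + \sigma_j}{d(c_i, c_j)}$$

with the usual conventions: $a_i$ mean distance to own-cluster co-members,
$b_i$ the best other-cluster mean distance, singleton clusters contributing
$s_i = 0$; $\sigma_i$ the mean distance to the cluster centroid. Both are
implemented directly from the formulas and verified against brute-force
evaluation to $10^{-9}$ in the tests. The cluster count is a parameter: use
the planted/known module count when one exists, otherwise a small sweep
($k \in \{5, 10, 20\}$) with the best silhouette reported is a reasonable
default. The combination rule (silhouette first, Davies–Bouldin tiebreak)
is this package's documented choice; so are the default non-dimension
hyperparameters (walk length 20, 10 walks per node, $p = q = 1$, context 10,
5 negatives), mid-grid values paired with the preferred 64-dimensional
space.

### Minimum spanning tree

The MST over the term-distance matrix sketches the global backbone of term
relationships. Construction is Kruskal's algorithm with a deterministic
tie-break (weight, then lexicographic `(term_a, term_b)`), validated against
exhaustive enumeration of all $5^3$ spanning trees on 5-node instances. The
CLI computes it on min–max-normalized distances; raw distances give the same
tree whenever normalization is monotone (it is, except in the degenerate
all-equal case), so the choice only matters for the exported weights.

### Cross-species projection

A second species' collection enters the host space in three steps. First,
ortholog conversion replaces each gene by *all* of its mapped targets
(one-to-many mappings keep every target; many-to-one collapses by set
semantics); unmapped genes are dropped, and terms losing every gene are
dropped *and reported* — ortholog attrition is heavy in practice and must be
visible, so the drop/coverage report is a mandatory output rather than an
option. Second, each converted term is placed in the host embedding by one
of two strategies:

* `neighbor_mean` (default): the arithmetic mean of the host vectors of the
  term's mapped genes — deterministic, training-free, and exact for a term
  whose gene set equals a host term's set up to embedding noise;
* `frozen_training`: the host graph is extended with the foreign term
  nodes, walks are re-simulated, and skip-gram training updates only the new
  rows while every host vector is frozen (and returned bit-identical).

The mechanism behind published cross-species embeddings of this kind is
typically underspecified; both plausible readings are provided, with the
deterministic one as default, and neither is labelled as canonical. Third,
nearest-term queries rank host *term* nodes (genes excluded) by distance,
ties broken by term id.

## The synthetic-data generator

`generate_collection` plants $M$ modules of terms: module pools are disjoint
gene sets of size `pool_size`, each term draws `genes_per_term` genes from
its module pool plus `noise_genes_per_term` from a shared background pool.
Disjoint pools keep the within/between overlap expectations analytically
orderable — between-module overlap can only arise through the background.
The default scale (4 modules × 15 terms, pools of 50, 20 genes per term, 3
background genes, background pool 200) yields a ~370-node graph that embeds
in well under a minute, which keeps multi-seed experiments minute-scale on
one CPU; these defaults are the package's study conditions and all
end-to-end checks run at them. `generate_ortholog_map` aliases a chosen
fraction of the genes one-to-one, and `generate_duplicated_foreign_terms`
emits foreign terms whose converted gene sets equal a host term's set — the
basis of the duplicate-recovery check, where the projected duplicate should
find its source as the nearest host term.

What the generator does *not* emulate: the heavy-tailed term-size
distribution of real collections (set sizes from a handful to thousands),
hierarchically nested terms (GO ancestors), many-to-many ortholog
relationships, and the $\sim 10^4$-term, $\sim 10^8$-pair scale of a full
MSigDB release. Passing the planted-module checks therefore demonstrates
that the machinery recovers designed structure under controlled noise — not
that any particular biological discovery is validated. Conversely, the
reliability-score scale (the 0–5 literature-support grade) is carried as an
annotation type only; its assignment is manual curation and is out of
computational scope.

## Numerical choices and degenerate inputs

* Constant inputs to min–max normalization map to zeros (not NaN).
* Hypergeometric inputs are validated ($0 \le k \le \min \le N$); the tail is
  computed by `phyper` and cross-checked against exhaustive enumeration for
  $N \le 12$ in the tests.
* Silhouette on singleton clusters uses $s_i = 0$; Davies–Bouldin refuses
  coincident centroids (division by zero).
* k-means is `stats::kmeans` (Lloyd, seeded, single start); determinism
  under seed is part of the contract.
* The trainer's learning-rate schedule updates every 1024 tokens; `p`, `q`
  must be strictly positive; walk sampling uses direct normalization of the
  case weights (the distribution, not the mechanism, is the contract).
* A walk corpus referencing a node outside the graph is an error, as are
  non-symmetric or non-finite distance matrices for the MST, fractions
  outside $(0,1]$, and $k$ exceeding the point count in clustering.

## Problem sizes used in the checks

The shipped checks embed the default synthetic collection (60 terms, ~310
genes) at five seeds with the default configuration, compare within- against
between-module term distances, compare silhouette at the true module count
($k=4$) with $k=8$, correlate normalized distance with Jaccard over all 1770
pairs, and run the duplicate-recovery experiment with 10 duplicated terms
per seed. `scripts/acceptance.R` recomputes exactly these quantities from
scratch and writes them as JSON; the vignette intentionally quotes none of
the resulting numbers — run the script or the test suite to regenerate
them.

## Known limitations

* Embedding quality at very small collections (a handful of terms) is noisy;
  the pair table and MST remain well-defined but distances carry little
  signal.
* The hypergeometric universe default (genes present in the collection)
  understates $N$ relative to "all annotated genes", making p-values
  conservative-to-liberal depending on the collection's coverage; supply an
  explicit universe when it matters.
* `frozen_training` trains new rows against frozen context vectors that were
  themselves co-trained with the host corpus; its projections are noisier
  than `neighbor_mean` for duplicate-like terms, which is why the
  deterministic strategy is the default.
* Walks and training are single-threaded by design (bit-reproducibility
  under one seed); embedding a full MSigDB-scale collection is feasible but
  hour-scale, and the 2700-point grid is a cluster job.
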