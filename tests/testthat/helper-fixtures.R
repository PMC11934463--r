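# Shared fixtures built in code.

# Minimal path graph a - b - c realised bipartitely: term T1 = {GA, GC}.
# Node indices: GA = 0, GC = 1, T1 = 2.
path3_graph <- function() {
  build_graph(gs_collection(
    term_id = "T1", description = "path center", genes = list(c("GA", "GC"))
  ))
}

tiny_collection <- function(seed = 3L) {
  generate_collection(synthetic_spec(
    n_modules = 2L, terms_per_module = 4L, pool_size = 10L,
    genes_per_term = 5L, noise_genes_per_term = 1L,
    background_pool_size = 20L, seed = seed
  ))
}

small_config <- function(seed = 1L, d = 16L, epochs = 8L) {
  walk_config(dimensions = d, walk_length = 10L, walks_per_node = 5L,
              context_size = 5L, negative_samples = 5L, epochs = epochs,
              seed = seed)
}

# Full-scale study-condition embeddings shared by the acceptance checks:
# default planted-module collection (M = 4), default walk configuration,
# seeds 1..5. Computed once per test run.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_runs <- function() {
  if (is.null(.acceptance_cache$runs)) {
    .acceptance_cache$runs <- lapply(1:5, function(s) {
      coll <- generate_collection(synthetic_spec(seed = s))
      fit <- embed_collection(coll, walk_config(seed = s))
      list(seed = s, collection = coll, graph = fit$graph,
           embedding = fit$embedding)
    })
  }
  .acceptance_cache$runs
}
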