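#' Construct a random-walk / embedding configuration
#'
#' Hyperparameters of the biased second-order walk and the skip-gram
#' training: embedding dimension `d`, walk length (steps per walk), walks
#' started per node, return parameter `p` (propensity to revisit the
#' previous node), in-out parameter `q` (BFS/DFS balance), skip-gram context
#' window, negatives per positive, training epochs and the RNG seed.
#'
#' Defaults use the preferred 64-dimensional space with mid-grid values for
#' the remaining parameters.
#'
#' @param dimensions Embedding dimension `d` (>= 1).
#' @param walk_length Steps per walk (>= 1).
#' @param walks_per_node Walks started from every node (>= 1).
#' @param p Return parameter (> 0).
#' @param q In-out parameter (> 0).
#' @param context_size Skip-gram window (>= 1).
#' @param negative_samples Negatives per positive pair (>= 0).
#' @param epochs Training passes over the walk corpus (>= 1).
#' @param seed Integer seed driving walks and training.
#' @return A `walk_config` list.
#' @export
walk_config <- function(dimensions = 64L, walk_length = 20L,
                        walks_per_node = 10L, p = 1, q = 1,
                        context_size = 10L, negative_samples = 5L,
                        epochs = 40L, seed = 1L) {
  cfg <- list(
    dimensions = as.integer(dimensions),
    walk_length = as.integer(walk_length),
    walks_per_node = as.integer(walks_per_node),
    p = as.numeric(p),
    q = as.numeric(q),
    context_size = as.integer(context_size),
    negative_samples = as.integer(negative_samples),
    epochs = as.integer(epochs),
    seed = as.integer(seed)
  )
  stopifnot(cfg$p > 0, cfg$q > 0, cfg$walk_length >= 1L, cfg$context_size >= 1L,
            cfg$dimensions >= 1L, cfg$epochs >= 1L, cfg$walks_per_node >= 1L,
            cfg$negative_samples >= 0L)
  structure(cfg, class = "walk_config")
}

#' @export
print.walk_config <- function(x, ...) {
  cat("<walk_config> d =", x$dimensions, " walk_length =", x$walk_length,
      " r =", x$walks_per_node, " p =", x$p, " q =", x$q,
      " context =", x$context_size, " negatives =", x$negative_samples,
      " epochs =", x$epochs, " seed =", x$seed, "\n")
  invisible(x)
}

#' The full hyperparameter search grid
#'
#' Cartesian product of the search values: dimensions \{32, 64\}, walk length
#' \{10, 20, 30\}, p and q \{0.25, 0.5, 1, 2, 4\}, context size \{10, 20\},
#' negative samples \{1, 5, 10\}, walks per node \{10, 20, 30\} — 2700
#' configurations, each trained for 40 epochs.
#'
#' @param seed Seed stored in every configuration.
#' @return Tibble with one row per configuration and the `walk_config`
#'   field names as columns; convert a row with [as_walk_config()].
#' @export
hyperparameter_grid <- function(seed = 1L) {
  grid <- tidyr::expand_grid(
    dimensions = c(32L, 64L),
    walk_length = c(10L, 20L, 30L),
    p = c(0.25, 0.5, 1, 2, 4),
    q = c(0.25, 0.5, 1, 2, 4),
    context_size = c(10L, 20L),
    negative_samples = c(1L, 5L, 10L),
    walks_per_node = c(10L, 20L, 30L)
  )
  grid$epochs <- 40L
  grid$seed <- as.integer(seed)
  grid
}

#' Coerce a one-row config data frame to a `walk_config`
#' @param row One-row data frame with `walk_config` field names.
#' @return A [walk_config()].
#' @export
as_walk_config <- function(row) {
  stopifnot(nrow(row) == 1L)
  walk_config(
    dimensions = row$dimensions, walk_length = row$walk_length,
    walks_per_node = row$walks_per_node, p = row$p, q = row$q,
    context_size = row$context_size, negative_samples = row$negative_samples,
    epochs = row$epochs, seed = row$seed
  )
}

#' Second-order transition distribution of the biased walk
#'
#' Given the previous node `v` and the current node, each neighbor `x` of the
#' current node gets unnormalized weight `1/p` if `x = v` (shortest-path
#' distance `d(v,x) = 0`), `1` if `x` is adjacent to `v` (`d(v,x) = 1`), and
#' `1/q` otherwise (`d(v,x) = 2`); weights are normalized to probabilities.
#' On a bipartite graph the middle case is unreachable for `x != v` because
#' `v` and `x` lie in the same partition.
#'
#' @param graph A `term_graph`.
#' @param previous,current 0-based node indices; must be adjacent.
#' @param config A [walk_config()] (only `p` and `q` are used).
#' @return Tibble with columns `candidate` (0-based neighbor of `current`)
#'   and `probability`, summing to 1.
#' @export
transition_distribution <- function(graph, previous, current, config = walk_config()) {
  nb_cur <- neighbors(graph, current)
  if (!(previous %in% nb_cur)) {
    stop("previous node ", previous, " is not adjacent to current node ",
         current, call. = FALSE)
  }
  nb_prev <- neighbors(graph, previous)
  w <- vapply(nb_cur, function(x) {
    if (x == previous) 1 / config$p
    else if (x %in% nb_prev) 1
    else 1 / config$q
  }, numeric(1))
  tibble::tibble(candidate = nb_cur, probability = w / sum(w))
}

#' Simulate biased random walks over a graph
#'
#' Starts exactly `walks_per_node` walks from every node, visiting nodes in a
#' freshly shuffled order on each pass. The first step (no predecessor) is
#' uniform over the start node's neighbors; later steps follow
#' [transition_distribution()]. Deterministic under `config$seed`.
#'
#' @param graph A `term_graph`.
#' @param config A [walk_config()].
#' @return A `walk_corpus`: list of integer vectors of 0-based node indices,
#'   each of length at most `walk_length + 1`.
#' @export
simulate_walks <- function(graph, config = walk_config()) {
  stopifnot(inherits(graph, "term_graph"), inherits(config, "walk_config"))
  walks <- cpp_simulate_walks(
    adjacency = graph$adjacency,
    p = config$p, q = config$q,
    walk_length = config$walk_length,
    walks_per_node = config$walks_per_node,
    seed = config$seed
  )
  structure(walks, class = "walk_corpus",
            n_nodes = graph$index$m + graph$index$n)
}

#' Train node embeddings from a walk corpus
#'
#' Skip-gram with negative sampling over (center, context) pairs within each
#' walk's context window; negatives are drawn from the corpus unigram
#' distribution raised to the 3/4 power; stochastic gradient descent with a
#' linearly decaying learning rate (initial 0.025). The center-vector matrix
#' is returned. Deterministic under `config$seed`.
#'
#' @param corpus A [simulate_walks()] result.
#' @param graph The source `term_graph`.
#' @param config A [walk_config()].
#' @param learning_rate Initial SGD learning rate.
#' @return A `node_embedding`: matrix `vectors` of one row per node (genes
#'   then terms, rownames = node names), plus the `index` and `config`.
#' @export
train_embeddings <- function(corpus, graph, config = walk_config(),
                             learning_rate = 0.025) {
  stopifnot(inherits(graph, "term_graph"), inherits(config, "walk_config"))
  if (length(corpus) == 0L) stop("empty walk corpus", call. = FALSE)
  n_nodes <- graph$index$m + graph$index$n
  mat <- cpp_train_sgns(
    walks = unclass(corpus), n_nodes = n_nodes, d = config$dimensions,
    window = config$context_size, negative = config$negative_samples,
    epochs = config$epochs, lr0 = learning_rate,
    seed = config$seed + 1L
  )
  if (any(!is.finite(mat))) stop("non-finite entries in trained embedding", call. = FALSE)
  rownames(mat) <- node_names(graph$index)
  structure(
    list(vectors = mat, d = config$dimensions, index = graph$index,
         config = config),
    class = "node_embedding"
  )
}

#' @export
print.node_embedding <- function(x, ...) {
  cat("<node_embedding> ", nrow(x$vectors), " nodes x d = ", x$d,
      " (", x$index$m, " genes, ", x$index$n, " terms)\n", sep = "")
  invisible(x)
}

#' Embed a gene-set collection end to end
#'
#' Builds the bipartite graph, simulates walks and trains embeddings.
#'
#' @param collection A [gs_collection()].
#' @param config A [walk_config()].
#' @return List with elements `graph` (`term_graph`) and `embedding`
#'   (`node_embedding`).
#' @export
embed_collection <- function(collection, config = walk_config()) {
  graph <- build_graph(collection)
  corpus <- simulate_walks(graph, config)
  embedding <- train_embeddings(corpus, graph, config)
  list(graph = graph, embedding = embedding)
}

#' Tidy a node embedding into a long-friendly tibble
#'
#' @param x A `node_embedding`.
#' @param ... Unused.
#' @return Tibble with `node`, `partition` and `v1..vd` columns.
#' @method tidy node_embedding
#' @export
tidy.node_embedding <- function(x, ...) {
  vec <- x$vectors
  colnames(vec) <- paste0("v", seq_len(ncol(vec)))
  dplyr::bind_cols(
    tibble::tibble(
      node = rownames(vec),
      partition = rep(c("gene", "term"), c(x$index$m, x$index$n))
    ),
    tibble::as_tibble(vec)
  )
}

#' @method glance node_embedding
#' @export
glance.node_embedding <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$vectors), n_genes = x$index$m, n_terms = x$index$n,
    d = x$d, p = x$config$p, q = x$config$q, epochs = x$config$epochs,
    seed = x$config$seed
  )
}

#' Write embeddings as TSV (node_name, partition, v1..vd)
#' @param embedding A `node_embedding`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_embeddings <- function(embedding, path) {
  readr::write_tsv(tidy(embedding), path)
  invisible(path)
}

#' Read embeddings written by [write_embeddings()]
#' @param path TSV path.
#' @return A `node_embedding` (with a reconstructed index; `config` is NULL).
#' @export
read_embeddings <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("node", "partition") %in% names(df)))
  vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
  vec <- as.matrix(df[vcols])
  rownames(vec) <- df$node
  genes <- df$node[df$partition == "gene"]
  terms <- df$node[df$partition == "term"]
  m <- length(genes)
  index <- structure(
    list(gene_to_index = setNames(seq_along(genes) - 1L, genes),
         term_to_index = setNames(m + seq_along(terms) - 1L, terms),
         m = m, n = length(terms)),
    class = "node_index"
  )
  structure(list(vectors = vec, d = ncol(vec), index = index, config = NULL),
            class = "node_embedding")
}

#' Write a walk configuration as a key/value text file
#' @param config A [walk_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_walk_config <- function(config, path) {
  stopifnot(inherits(config, "walk_config"))
  writeLines(paste(names(config), unlist(config), sep = "\t"), path)
  invisible(path)
}

#' Read a walk configuration written by [write_walk_config()]
#' @param path Key/value file path.
#' @return A [walk_config()].
#' @export
read_walk_config <- function(path) {
  kv <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
  vals <- setNames(vapply(kv, `[[`, character(1), 2L),
                   vapply(kv, `[[`, character(1), 1L))
  do.call(walk_config, as.list(vals))
}
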