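#' Build the node index of a gene-term bipartite graph
#'
#' Genes are indexed in first-appearance order over `0..m-1`; terms in
#' collection order over `m..m+n-1`. The node universe has `m + n` nodes and
#' genes never appearing in any term are absent by construction.
#'
#' @param collection A [gs_collection()].
#' @return A `node_index` object: named integer vectors `gene_to_index` and
#'   `term_to_index` (0-based), plus counts `m` and `n`.
#' @export
build_index <- function(collection) {
  stopifnot(inherits(collection, "gs_collection"))
  if (nrow(collection) == 0L) stop("empty collection", call. = FALSE)
  genes <- unique(unlist(collection$genes, use.names = FALSE))
  m <- length(genes)
  n <- nrow(collection)
  structure(
    list(
      gene_to_index = setNames(seq_len(m) - 1L, genes),
      term_to_index = setNames(m + seq_len(n) - 1L, collection$term_id),
      m = m,
      n = n
    ),
    class = "node_index"
  )
}

#' @export
print.node_index <- function(x, ...) {
  cat("<node_index> m =", x$m, "genes [0..", x$m - 1L, "], n =", x$n,
      "terms [", x$m, "..", x$m + x$n - 1L, "]\n")
  invisible(x)
}

#' Node names in index order
#' @param index A `node_index`.
#' @return Character vector of length `m + n`: gene symbols then term ids.
#' @export
node_names <- function(index) {
  stopifnot(inherits(index, "node_index"))
  c(names(index$gene_to_index), names(index$term_to_index))
}

#' Construct the gene-term bipartite graph
#'
#' One edge per (gene, term) incidence; the edge count equals the sum of
#' per-term gene-set sizes because gene sets are deduplicated at load time.
#'
#' @param collection A [gs_collection()].
#' @param index A [build_index()] result covering every gene and term.
#' @return A `term_graph`: the index, an `edges` tibble of 0-based
#'   `(gene_index, term_index)` pairs, and a sorted adjacency list.
#' @export
build_graph <- function(collection, index = build_index(collection)) {
  stopifnot(inherits(collection, "gs_collection"), inherits(index, "node_index"))
  missing_terms <- setdiff(collection$term_id, names(index$term_to_index))
  if (length(missing_terms) > 0L) {
    stop("terms missing from index: ", paste(missing_terms, collapse = ", "),
         call. = FALSE)
  }
  all_genes <- unique(unlist(collection$genes, use.names = FALSE))
  missing_genes <- setdiff(all_genes, names(index$gene_to_index))
  if (length(missing_genes) > 0L) {
    stop("genes missing from index: ",
         paste(head(missing_genes, 5L), collapse = ", "), call. = FALSE)
  }
  edges <- tibble::tibble(
    gene_index = unname(index$gene_to_index[unlist(collection$genes, use.names = FALSE)]),
    term_index = rep(unname(index$term_to_index[collection$term_id]),
                     lengths(collection$genes))
  )
  n_nodes <- index$m + index$n
  adj <- vector("list", n_nodes)
  split_g <- split(edges$term_index, edges$gene_index)
  split_t <- split(edges$gene_index, edges$term_index)
  for (nm in names(split_g)) adj[[as.integer(nm) + 1L]] <- sort(unique(split_g[[nm]]))
  for (nm in names(split_t)) adj[[as.integer(nm) + 1L]] <- sort(unique(split_t[[nm]]))
  structure(
    list(index = index, edges = edges, adjacency = adj),
    class = "term_graph"
  )
}

#' @export
print.term_graph <- function(x, ...) {
  cat("<term_graph> |V| =", x$index$m + x$index$n,
      "(", x$index$m, "genes +", x$index$n, "terms ), |E| =",
      nrow(x$edges), "\n")
  invisible(x)
}

#' Neighbors of a node
#'
#' @param graph A `term_graph`.
#' @param node 0-based node index in `0..m+n-1`.
#' @return Sorted, duplicate-free integer vector of 0-based neighbor indices;
#'   gene nodes return term indices and vice versa.
#' @export
neighbors <- function(graph, node) {
  stopifnot(inherits(graph, "term_graph"))
  n_nodes <- graph$index$m + graph$index$n
  if (length(node) != 1L || is.na(node) || node < 0L || node >= n_nodes) {
    stop("node index out of range [0, ", n_nodes - 1L, "]: ", node, call. = FALSE)
  }
  graph$adjacency[[as.integer(node) + 1L]]
}

#' Node table of a graph
#' @param graph A `term_graph`.
#' @return Tibble with columns `index` (0-based), `name`,
#'   `partition` (`"gene"` or `"term"`).
#' @export
node_table <- function(graph) {
  stopifnot(inherits(graph, "term_graph"))
  idx <- graph$index
  tibble::tibble(
    index = seq_len(idx$m + idx$n) - 1L,
    name = node_names(idx),
    partition = rep(c("gene", "term"), c(idx$m, idx$n))
  )
}

#' Export a graph as edge-list and node-table TSVs
#' @param graph A `term_graph`.
#' @param edge_path,node_path Output paths.
#' @return Invisibly, the two paths.
#' @export
export_graph <- function(graph, edge_path, node_path) {
  stopifnot(inherits(graph, "term_graph"))
  readr::write_tsv(graph$edges, edge_path)
  readr::write_tsv(node_table(graph), node_path)
  invisible(c(edge_path, node_path))
}
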