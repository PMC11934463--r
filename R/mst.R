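#' Minimum spanning tree over terms
#'
#' Kruskal construction on a symmetric term-distance matrix with a
#' deterministic tie-break: candidate edges are sorted by weight, then
#' lexicographically by `(term_a, term_b)`. The result sketches the global
#' backbone of term relationships.
#'
#' @param distance_matrix Finite symmetric matrix with zero diagonal and
#'   at least 2 terms; dimnames give term ids (generated if absent).
#' @return A `term_tree`: `edges` tibble `(term_a, term_b, weight)` with
#'   exactly `n - 1` rows, plus `n_terms`.
#' @export
minimum_spanning_tree <- function(distance_matrix) {
  dm <- as.matrix(distance_matrix)
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 terms for a spanning tree", call. = FALSE)
  if (ncol(dm) != n) stop("distance matrix must be square", call. = FALSE)
  if (any(!is.finite(dm))) stop("non-finite entries in distance matrix", call. = FALSE)
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix must be symmetric", call. = FALSE)
  ids <- rownames(dm) %||% paste0("T", seq_len(n))

  ut <- which(upper.tri(dm), arr.ind = TRUE)
  cand <- tibble::tibble(
    a = ut[, "row"], b = ut[, "col"], weight = dm[ut],
    id_a = pmin(ids[ut[, "row"]], ids[ut[, "col"]]),
    id_b = pmax(ids[ut[, "row"]], ids[ut[, "col"]])
  )
  cand <- cand[order(cand$weight, cand$id_a, cand$id_b), ]

  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- logical(nrow(cand))
  taken <- 0L
  for (e in seq_len(nrow(cand))) {
    ra <- find(cand$a[e])
    rb <- find(cand$b[e])
    if (ra != rb) {
      parent[ra] <- rb
      keep[e] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  edges <- cand[keep, c("id_a", "id_b", "weight")]
  names(edges) <- c("term_a", "term_b", "weight")
  structure(list(edges = tibble::as_tibble(edges), n_terms = n),
            class = "term_tree")
}

#' @export
print.term_tree <- function(x, ...) {
  cat("<term_tree> ", x$n_terms, " terms, ", nrow(x$edges),
      " edges, total weight ", signif(sum(x$edges$weight), 6), "\n", sep = "")
  invisible(x)
}

#' @method tidy term_tree
#' @export
tidy.term_tree <- function(x, ...) x$edges

#' Plot a term tree with a force-directed layout
#'
#' @param object A `term_tree`.
#' @param ... Unused.
#' @return A ggplot object; edge alpha scales inversely with weight.
#' @method autoplot term_tree
#' @export
autoplot.term_tree <- function(object, ...) {
  g <- igraph::graph_from_data_frame(object$edges, directed = FALSE)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  seg <- dplyr::left_join(
    dplyr::left_join(object$edges, nodes, by = c(term_a = "name")),
    nodes, by = c(term_b = "name"), suffix = c("", "end")
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, alpha = -.data$weight)) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::guides(alpha = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Minimum spanning tree over terms")
}

#' Export a term tree as edge-list TSV and GraphML
#'
#' @param tree A [minimum_spanning_tree()] result with at least 1 edge.
#' @param edge_path Edge-list TSV path (`term_a`, `term_b`, `weight`).
#' @param graphml_path Optional GraphML path (weight stored as an edge
#'   attribute); skipped when `NULL`.
#' @return Invisibly, the written paths.
#' @export
export_tree <- function(tree, edge_path, graphml_path = NULL) {
  stopifnot(inherits(tree, "term_tree"))
  if (nrow(tree$edges) == 0L) stop("refusing to export an empty tree", call. = FALSE)
  readr::write_tsv(tree$edges, edge_path)
  written <- edge_path
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(tree$edges, directed = FALSE)
    igraph::E(g)$weight <- tree$edges$weight
    igraph::write_graph(g, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  invisible(written)
}

#' Read a term tree back from a GraphML file
#' @param path GraphML path written by [export_tree()].
#' @return A `term_tree`.
#' @export
read_tree_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- tibble::tibble(
    term_a = pmin(el$from, el$to),
    term_b = pmax(el$from, el$to),
    weight = el$weight
  )
  structure(list(edges = edges, n_terms = igraph::vcount(g)),
            class = "term_tree")
}
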