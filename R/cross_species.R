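#' Convert a collection to the host species' gene namespace
#'
#' Replaces every gene by all of its ortholog targets (one-to-many mappings
#' keep all targets; many-to-one collapses by set semantics). Unmapped genes
#' are dropped; terms whose converted set becomes empty are dropped and
#' reported.
#'
#' @param collection A [gs_collection()] in the source species' namespace.
#' @param orthologs An [ortholog_map()] (source -> target symbols).
#' @return The converted `gs_collection`; attribute `drop_report` is a
#'   tibble (`term_id`, `n_genes`, `n_mapped`, `coverage`, `status`) with one
#'   row per input term.
#' @export
convert_collection <- function(collection, orthologs) {
  stopifnot(inherits(collection, "gs_collection"), inherits(orthologs, "ortholog_map"))
  targets <- split(orthologs$target, orthologs$source)
  converted <- lapply(collection$genes, function(g) {
    unique(unlist(targets[intersect(g, names(targets))], use.names = FALSE))
  })
  n_mapped_src <- vapply(collection$genes, function(g)
    sum(g %in% names(targets)), integer(1))
  keep <- lengths(converted) > 0L
  report <- tibble::tibble(
    term_id = collection$term_id,
    n_genes = lengths(collection$genes),
    n_mapped = n_mapped_src,
    coverage = n_mapped_src / lengths(collection$genes),
    status = ifelse(keep, "converted", "dropped")
  )
  if (!any(keep)) {
    stop("every term dropped: no gene has an ortholog mapping", call. = FALSE)
  }
  out <- gs_collection(
    term_id = collection$term_id[keep],
    description = collection$description[keep],
    genes = converted[keep],
    species_label = paste0(attr(collection, "species_label") %||% "unspecified",
                           " (ortholog-converted)")
  )
  attr(out, "drop_report") <- report
  out
}

#' Project foreign terms into a frozen host embedding space
#'
#' Places ortholog-converted terms from a second species into the host
#' (pre-trained) embedding. Two strategies:
#' * `neighbor_mean` (default): a term's vector is the arithmetic mean of
#'   the host vectors of its mapped genes — deterministic, no training.
#' * `frozen_training`: the host graph is extended with the foreign term
#'   nodes, walks are simulated on the extended graph, and skip-gram
#'   training updates ONLY the new term vectors while every host vector
#'   stays frozen.
#' Either way the host embedding is bit-unchanged.
#'
#' @param converted An ortholog-converted [gs_collection()] (host namespace).
#' @param host_graph The host `term_graph`.
#' @param host_embeddings The host `node_embedding`.
#' @param strategy `"neighbor_mean"` or `"frozen_training"`.
#' @param config A [walk_config()] (used by `frozen_training`).
#' @return A `projected_terms`: `vectors` (matrix, one row per projected
#'   foreign term), `strategy`, and a `coverage` tibble (`term_id`,
#'   `n_genes`, `n_mapped`, `coverage`, `status`); terms with no gene
#'   present among host gene nodes are dropped and reported.
#' @export
project_terms <- function(converted, host_graph, host_embeddings,
                          strategy = c("neighbor_mean", "frozen_training"),
                          config = walk_config()) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(converted, "gs_collection"),
            inherits(host_graph, "term_graph"),
            inherits(host_embeddings, "node_embedding"))
  host_genes <- names(host_graph$index$gene_to_index)
  mapped <- lapply(converted$genes, intersect, host_genes)
  keep <- lengths(mapped) > 0L
  coverage <- tibble::tibble(
    term_id = converted$term_id,
    n_genes = lengths(converted$genes),
    n_mapped = lengths(mapped),
    coverage = lengths(mapped) / lengths(converted$genes),
    status = ifelse(keep, "projected", "dropped")
  )
  if (!any(keep)) stop("no foreign term has a gene among host gene nodes", call. = FALSE)
  kept_ids <- converted$term_id[keep]
  kept_genes <- mapped[keep]
  d <- host_embeddings$d

  if (strategy == "neighbor_mean") {
    gv <- gene_vectors(host_embeddings)
    vec <- t(vapply(kept_genes, function(g)
      colMeans(gv[g, , drop = FALSE]), numeric(d)))
  } else {
    vec <- project_frozen_training(kept_ids, kept_genes, host_graph,
                                   host_embeddings, config)
  }
  rownames(vec) <- kept_ids
  structure(
    list(vectors = vec, strategy = strategy, coverage = coverage, d = d),
    class = "projected_terms"
  )
}

# Extend the host graph with foreign term nodes (indices m+n ...), walk, and
# train with all host rows frozen at their pre-trained values.
project_frozen_training <- function(kept_ids, kept_genes, host_graph,
                                    host_embeddings, config) {
  idx <- host_graph$index
  n_host <- idx$m + idx$n
  n_new <- length(kept_ids)
  adj <- host_graph$adjacency
  length(adj) <- n_host + n_new
  for (i in seq_len(n_new)) {
    gidx <- sort(unname(idx$gene_to_index[kept_genes[[i]]]))
    adj[[n_host + i]] <- gidx
    for (g in gidx) {
      adj[[g + 1L]] <- sort(c(adj[[g + 1L]], n_host + i - 1L))
    }
  }
  walks <- cpp_simulate_walks(adj, p = config$p, q = config$q,
                              walk_length = config$walk_length,
                              walks_per_node = config$walks_per_node,
                              seed = config$seed)
  d <- host_embeddings$d
  init <- rbind(
    host_embeddings$vectors,
    matrix(withr_seed(config$seed + 2L,
                      stats::runif(n_new * d, -0.5 / d, 0.5 / d)),
           nrow = n_new, ncol = d)
  )
  trainable <- c(rep(FALSE, n_host), rep(TRUE, n_new))
  mat <- cpp_train_sgns(
    walks = walks, n_nodes = n_host + n_new, d = d,
    window = config$context_size, negative = config$negative_samples,
    epochs = config$epochs, lr0 = 0.025, seed = config$seed + 3L,
    init = init, trainable = trainable
  )
  stopifnot(identical(mat[seq_len(n_host), , drop = FALSE],
                      unname(host_embeddings$vectors)))
  mat[n_host + seq_len(n_new), , drop = FALSE]
}

#' @export
print.projected_terms <- function(x, ...) {
  cat("<projected_terms> ", nrow(x$vectors), " foreign terms in d = ", x$d,
      " host space (strategy: ", x$strategy, ")\n", sep = "")
  invisible(x)
}

#' @method tidy projected_terms
#' @export
tidy.projected_terms <- function(x, ...) {
  vec <- x$vectors
  colnames(vec) <- paste0("v", seq_len(ncol(vec)))
  dplyr::bind_cols(tibble::tibble(term_id = rownames(vec)),
                   tibble::as_tibble(vec))
}

#' Nearest host terms to a query vector
#'
#' Search is restricted to host TERM nodes (gene nodes are excluded);
#' results ascend by distance with ties broken by term id. If `k` exceeds
#' the number of host terms, all terms are returned.
#'
#' @param query Numeric vector of length `d` (e.g. one row of a
#'   [project_terms()] result).
#' @param host_embeddings The host `node_embedding`.
#' @param index Host `node_index` (defaults to the embedding's).
#' @param k Number of neighbors, `k >= 1`.
#' @param metric `"euclidean"` or `"cosine"`.
#' @return Tibble `(term_id, distance)` of up to `k` rows, ascending.
#' @export
nearest_terms <- function(query, host_embeddings, index = host_embeddings$index,
                          k = 5L, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (!is.numeric(k) || length(k) != 1L || k < 1L) {
    stop("k must be a positive integer", call. = FALSE)
  }
  tv <- host_embeddings$vectors[names(index$term_to_index), , drop = FALSE]
  if (length(query) != ncol(tv)) stop("query dimension mismatch", call. = FALSE)
  if (metric == "euclidean") {
    dists <- sqrt(colSums((t(tv) - query)^2))
  } else {
    qn <- sqrt(sum(query^2))
    tn <- sqrt(rowSums(tv^2))
    dists <- 1 - as.vector(tv %*% query) / (qn * tn)
  }
  ord <- order(dists, rownames(tv))
  ord <- ord[seq_len(min(k, length(ord)))]
  tibble::tibble(term_id = rownames(tv)[ord], distance = unname(dists[ord]))
}

#' Nearest-host-term table for every projected foreign term
#'
#' @param projected A [project_terms()] result.
#' @param host_embeddings The host `node_embedding`.
#' @param k Neighbors per foreign term.
#' @param metric Distance metric.
#' @return Tibble `(foreign_term, rank, term_id, distance)`.
#' @export
nearest_term_table <- function(projected, host_embeddings, k = 5L,
                               metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  stopifnot(inherits(projected, "projected_terms"))
  purrr::map_dfr(rownames(projected$vectors), function(ft) {
    nb <- nearest_terms(projected$vectors[ft, ], host_embeddings,
                        k = k, metric = metric)
    tibble::tibble(foreign_term = ft, rank = seq_len(nrow(nb)),
                   term_id = nb$term_id, distance = nb$distance)
  })
}
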