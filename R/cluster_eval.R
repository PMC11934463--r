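#' k-means clustering of embedding vectors
#'
#' Seeded Lloyd iterations via [stats::kmeans()]; within-cluster sum of
#' squares is non-increasing across iterations by construction of the
#' algorithm. Internal validation metrics are attached.
#'
#' @param points Numeric matrix (rows = points) or a `node_embedding`
#'   (clusters all nodes; use [term_vectors()] for terms only).
#' @param k Number of clusters, `2 <= k <= nrow(points)`.
#' @param seed Integer seed for the initialization.
#' @param iter_max Maximum Lloyd iterations.
#' @return An `embedding_clustering`: `labels` (0-based cluster ids, named by
#'   rowname), `k`, `centroids`, `silhouette`, `davies_bouldin`.
#' @export
kmeans_embedding <- function(points, k, seed = 1L, iter_max = 100L) {
  if (inherits(points, "node_embedding")) points <- points$vectors
  points <- as.matrix(points)
  if (k > nrow(points)) stop("k exceeds the number of points", call. = FALSE)
  if (k < 2L) stop("k must be at least 2 for metric computation", call. = FALSE)
  km <- withr_seed(seed, {
    kmeans(points, centers = k, iter.max = iter_max, nstart = 1L,
           algorithm = "Lloyd")
  })
  labels <- km$cluster - 1L
  names(labels) <- rownames(points)
  structure(
    list(labels = labels, k = k, centroids = km$centers,
         silhouette = silhouette_score(points, labels),
         davies_bouldin = davies_bouldin_score(points, labels),
         tot_withinss = km$tot.withinss),
    class = "embedding_clustering"
  )
}

# evaluate expr under a temporary RNG state, restoring the caller's state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.embedding_clustering <- function(x, ...) {
  cat("<embedding_clustering> k =", x$k,
      " silhouette =", signif(x$silhouette, 4),
      " Davies-Bouldin =", signif(x$davies_bouldin, 4), "\n")
  invisible(x)
}

#' @method glance embedding_clustering
#' @export
glance.embedding_clustering <- function(x, ...) {
  tibble::tibble(k = x$k, silhouette = x$silhouette,
                 davies_bouldin = x$davies_bouldin,
                 tot_withinss = x$tot_withinss)
}

#' @method tidy embedding_clustering
#' @export
tidy.embedding_clustering <- function(x, ...) {
  tibble::tibble(point = names(x$labels) %||% as.character(seq_along(x$labels)),
                 cluster = unname(x$labels))
}

#' Mean silhouette score of a clustering
#'
#' Per point, `s_i = (b_i - a_i) / max(a_i, b_i)` where `a_i` is the mean
#' euclidean distance to co-members of its own cluster and `b_i` the minimum
#' over other clusters of the mean distance to that cluster's members;
#' singleton clusters contribute `s_i = 0`. The mean over points lies in
#' `[-1, 1]`; higher is better.
#'
#' @param points Numeric matrix, one row per point.
#' @param labels Integer cluster labels (any coding), one per row.
#' @return The mean silhouette.
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(factor(labels))
  if (length(labels) != nrow(points)) stop("labels/points length mismatch", call. = FALSE)
  k <- max(labels)
  if (k < 2L) stop("silhouette requires at least 2 clusters", call. = FALSE)
  dm <- as.matrix(dist(points))
  n <- nrow(points)
  sizes <- tabulate(labels, k)
  # mean distance from each point to each cluster
  cl_sum <- vapply(seq_len(k), function(c) rowSums(dm[, labels == c, drop = FALSE]),
                   numeric(n))
  s <- vapply(seq_len(n), function(i) {
    ci <- labels[i]
    if (sizes[ci] == 1L) return(0)
    a_i <- cl_sum[i, ci] / (sizes[ci] - 1L)
    b_i <- min(cl_sum[i, -ci] / sizes[-ci])
    (b_i - a_i) / max(a_i, b_i)
  }, numeric(1))
  mean(s)
}

#' Davies-Bouldin score of a clustering
#'
#' `DB = (1/k) * sum_i max_{j != i} (sigma_i + sigma_j) / d(c_i, c_j)` where
#' `sigma_i` is the mean euclidean distance of cluster-i points to their
#' centroid and `d(c_i, c_j)` the centroid distance. Lower is better; 0 when
#' every cluster has zero spread.
#'
#' @inheritParams silhouette_score
#' @return The Davies-Bouldin index (non-negative).
#' @export
davies_bouldin_score <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(factor(labels))
  if (length(labels) != nrow(points)) stop("labels/points length mismatch", call. = FALSE)
  k <- max(labels)
  if (k < 2L) stop("Davies-Bouldin requires at least 2 clusters", call. = FALSE)
  centroids <- do.call(rbind, lapply(seq_len(k), function(c)
    colMeans(points[labels == c, , drop = FALSE])))
  sigma <- vapply(seq_len(k), function(c) {
    pts <- points[labels == c, , drop = FALSE]
    mean(sqrt(rowSums((pts - rep(centroids[c, ], each = nrow(pts)))^2)))
  }, numeric(1))
  cd <- as.matrix(dist(centroids))
  if (any(cd[upper.tri(cd)] == 0)) {
    stop("coincident centroids: Davies-Bouldin undefined", call. = FALSE)
  }
  ratios <- outer(sigma, sigma, `+`) / cd
  diag(ratios) <- -Inf
  mean(apply(ratios, 1L, max))
}

#' Evaluate a hyperparameter grid by clustering quality
#'
#' Embeds the collection once per configuration, clusters the term vectors
#' with k-means and records silhouette and Davies-Bouldin.
#'
#' @param collection A [gs_collection()].
#' @param grid Configurations as rows (see [hyperparameter_grid()]); use
#'   `head(grid, limit)` style subsampling for tractable sweeps.
#' @param k Cluster count for evaluation.
#' @param seed Clustering seed.
#' @return The grid with `silhouette`, `davies_bouldin` and `rank` columns,
#'   best configuration first.
#' @export
evaluate_grid <- function(collection, grid, k = 5L, seed = 1L) {
  stopifnot(nrow(grid) >= 1L)
  scores <- purrr::map(seq_len(nrow(grid)), function(i) {
    cfg <- as_walk_config(grid[i, ])
    fit <- embed_collection(collection, cfg)
    cl <- kmeans_embedding(term_vectors(fit$embedding), k = k, seed = seed)
    tibble::tibble(silhouette = cl$silhouette, davies_bouldin = cl$davies_bouldin)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(scores))
  out <- dplyr::arrange(out, dplyr::desc(.data$silhouette), .data$davies_bouldin)
  out$rank <- seq_len(nrow(out))
  out
}

#' Select the best configuration from grid-evaluation results
#'
#' Ranks by silhouette descending; Davies-Bouldin ascending breaks ties.
#' Deterministic: input order never changes the selection (row order among
#' fully tied configurations is resolved by the configuration fields).
#'
#' @param results Data frame with configuration columns plus `silhouette`
#'   and `davies_bouldin`.
#' @return The selected configuration as a [walk_config()].
#' @export
select_hyperparameters <- function(results) {
  if (is.null(results) || nrow(results) == 0L) stop("empty results", call. = FALSE)
  cfg_cols <- intersect(
    c("dimensions", "walk_length", "p", "q", "context_size",
      "negative_samples", "walks_per_node", "epochs", "seed"),
    names(results)
  )
  ord <- results[do.call(order, c(
    list(-results$silhouette, results$davies_bouldin),
    lapply(cfg_cols, function(cc) results[[cc]])
  )), , drop = FALSE]
  as_walk_config(ord[1L, ])
}

#' Term-node vectors of an embedding
#' @param embedding A `node_embedding`.
#' @return Matrix of term vectors (rownames = term ids).
#' @export
term_vectors <- function(embedding) {
  stopifnot(inherits(embedding, "node_embedding"))
  embedding$vectors[names(embedding$index$term_to_index), , drop = FALSE]
}

#' Gene-node vectors of an embedding
#' @param embedding A `node_embedding`.
#' @return Matrix of gene vectors (rownames = gene symbols).
#' @export
gene_vectors <- function(embedding) {
  stopifnot(inherits(embedding, "node_embedding"))
  embedding$vectors[names(embedding$index$gene_to_index), , drop = FALSE]
}

#' Plot grid-evaluation results
#'
#' @param results An [evaluate_grid()] result.
#' @return A ggplot object: silhouette (higher better) against
#'   Davies-Bouldin (lower better), colored by embedding dimension.
#' @export
plot_grid_evaluation <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$davies_bouldin, y = .data$silhouette,
                               color = factor(.data$dimensions))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Davies-Bouldin (lower is better)",
                  y = "Silhouette (higher is better)", color = "d")
}
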