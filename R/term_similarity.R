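#' Jaccard index between two gene sets
#'
#' `|A intersect B| / |A union B|`: 1 iff the sets are equal, 0 iff disjoint,
#' symmetric in its arguments.
#'
#' @param set_a,set_b Non-empty character vectors (treated as sets).
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' jaccard_index(c("a", "b", "c"), c("c", "d"))  # 1/4
jaccard_index <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_a) == 0L || length(set_b) == 0L) {
    stop("gene sets must be non-empty", call. = FALSE)
  }
  inter <- length(intersect(set_a, set_b))
  inter / (length(set_a) + length(set_b) - inter)
}

#' Hypergeometric upper-tail overlap probability
#'
#' The probability of observing at least `k` shared genes between a set of
#' size `size_a` and a set of size `size_b` drawn from a universe of `N`
#' genes: `P(X >= k)` for `X ~ Hypergeometric(N, size_a, size_b)`. This is
#' the overlap-significance screen applied at `p < 0.05`.
#'
#' @param k Observed overlap, `0 <= k <= min(size_a, size_b)`.
#' @param size_a,size_b Set sizes.
#' @param universe Universe size `N >= max(size_a, size_b)`.
#' @return Upper-tail probability in `(0, 1]`.
#' @export
hypergeometric_pvalue <- function(k, size_a, size_b, universe) {
  if (any(c(k, size_a, size_b, universe) < 0) ||
      k > min(size_a, size_b) || max(size_a, size_b) > universe) {
    stop("inconsistent counts: need 0 <= k <= min(size_a, size_b) <= N",
         call. = FALSE)
  }
  phyper(k - 1, m = size_a, n = universe - size_a, k = size_b,
         lower.tail = FALSE)
}

#' Pairwise distances between term embeddings
#'
#' @param embeddings A `node_embedding` covering every term node.
#' @param index A `node_index` (defaults to the embedding's own index).
#' @param metric `"euclidean"` or `"cosine"` (cosine distance =
#'   1 - cosine similarity).
#' @return Symmetric matrix over terms (dimnames = term ids), zero diagonal.
#' @export
pairwise_term_distances <- function(embeddings, index = embeddings$index,
                                    metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  stopifnot(inherits(embeddings, "node_embedding"), inherits(index, "node_index"))
  term_ids <- names(index$term_to_index)
  missing <- setdiff(term_ids, rownames(embeddings$vectors))
  if (length(missing) > 0L) {
    stop("terms without embedding vectors: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  tv <- embeddings$vectors[term_ids, , drop = FALSE]
  if (metric == "euclidean") {
    dm <- as.matrix(dist(tv, method = "euclidean"))
  } else {
    nrm <- sqrt(rowSums(tv^2))
    if (any(nrm == 0)) stop("zero-norm vector: cosine distance undefined", call. = FALSE)
    sim <- tcrossprod(tv / nrm)
    dm <- 1 - sim
    dm[dm < 0] <- 0
  }
  diag(dm) <- 0
  dimnames(dm) <- list(term_ids, term_ids)
  dm
}

#' Min-max normalization to [0, 1]
#'
#' `(x - min) / (max - min)`; a constant input maps to all zeros.
#'
#' @param values Non-empty numeric vector.
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(values) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Distance threshold selecting the closest fraction of pairs
#'
#' Returns the value at the `ceiling(fraction * N)`-th position of the
#' ascending sort; pairs with distance at or below the threshold are the
#' "top fraction" (closest) pairs, ties included.
#'
#' @param distances Non-empty numeric vector.
#' @param fraction Fraction in `(0, 1]`; 0.05 marks the top-5% screen.
#' @return The threshold value.
#' @export
top_fraction_threshold <- function(distances, fraction = 0.05) {
  if (length(distances) == 0L) stop("empty distances", call. = FALSE)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  sort(distances)[ceiling(fraction * length(distances))]
}

#' Assemble the term-pair table
#'
#' One row per unordered term pair with the three statistics of the
#' framework: Jaccard index of the gene sets, hypergeometric upper-tail
#' p-value of the overlap (universe = all distinct genes in the graph under
#' the default policy), and raw plus min-max-normalized embedding distance.
#' Normalization is global over all pairs of the run.
#'
#' @param graph A `term_graph` built from the collection.
#' @param embeddings A `node_embedding` for the same graph.
#' @param collection The [gs_collection()] behind the graph (provides the
#'   gene sets).
#' @param metric Distance metric, see [pairwise_term_distances()].
#' @param universe Hypergeometric universe policy: `"graph_genes"` (distinct
#'   genes in the graph) or an explicit integer.
#' @param adjust If `TRUE`, add a Benjamini-Hochberg adjusted p-value column
#'   `hypergeom_p_adj` (off by default; the screen uses raw p-values).
#' @return A tibble with columns `term_a`, `term_b`, `jaccard`,
#'   `hypergeom_p`, `raw_distance`, `norm_distance`, `rs` (`NA` unless
#'   annotated downstream).
#' @export
build_pair_table <- function(graph, embeddings, collection,
                             metric = c("euclidean", "cosine"),
                             universe = "graph_genes", adjust = FALSE) {
  metric <- match.arg(metric)
  stopifnot(inherits(graph, "term_graph"), inherits(collection, "gs_collection"))
  term_ids <- names(graph$index$term_to_index)
  if (!setequal(term_ids, collection$term_id)) {
    stop("collection terms do not match the graph's term nodes", call. = FALSE)
  }
  n <- length(term_ids)
  if (n < 2L) stop("need at least 2 terms to form pairs", call. = FALSE)
  N <- if (identical(universe, "graph_genes")) graph$index$m else as.integer(universe)

  gsets <- setNames(collection$genes, collection$term_id)[term_ids]
  sizes <- lengths(gsets)
  dm <- pairwise_term_distances(embeddings, graph$index, metric)

  ij <- which(upper.tri(dm), arr.ind = TRUE)
  ij <- ij[order(ij[, "row"], ij[, "col"]), , drop = FALSE]
  a <- ij[, "row"]
  b <- ij[, "col"]
  overlap <- mapply(function(i, j) length(intersect(gsets[[i]], gsets[[j]])), a, b)
  jac <- overlap / (sizes[a] + sizes[b] - overlap)
  pval <- phyper(overlap - 1, m = sizes[a], n = N - sizes[a], k = sizes[b],
                 lower.tail = FALSE)
  raw_d <- dm[cbind(a, b)]
  out <- tibble::tibble(
    term_a = term_ids[a],
    term_b = term_ids[b],
    jaccard = unname(jac),
    hypergeom_p = unname(pval),
    raw_distance = unname(raw_d),
    norm_distance = minmax_normalize(unname(raw_d)),
    rs = NA_integer_
  )
  if (adjust) {
    out$hypergeom_p_adj <- stats::p.adjust(out$hypergeom_p, method = "BH")
  }
  class(out) <- c("term_pair_table", class(out))
  out
}

#' Select the closest fraction of a pair table
#'
#' @param pairs A [build_pair_table()] result.
#' @param fraction Fraction in `(0, 1]`.
#' @param column Distance column used for thresholding.
#' @return The subset tibble (threshold stored as attribute `threshold`).
#' @export
top_pairs <- function(pairs, fraction = 0.05, column = "norm_distance") {
  thr <- top_fraction_threshold(pairs[[column]], fraction)
  out <- dplyr::filter(pairs, .data[[column]] <= thr)
  attr(out, "threshold") <- thr
  out
}

#' Attach a reliability-score annotation to pairs
#'
#' The reliability score is a manual 0-5 literature-support grade for a term
#' pair (5 = strong multi-study evidence ... 0 = no plausible association).
#' Its assignment is human curation; this helper only merges existing
#' annotations into the table.
#'
#' @param pairs A pair table.
#' @param annotations Tibble with `term_a`, `term_b`, `rs` (integer 0-5).
#' @return The pair table with `rs` filled where annotated.
#' @export
annotate_rs <- function(pairs, annotations) {
  stopifnot(all(c("term_a", "term_b", "rs") %in% names(annotations)))
  if (!all(annotations$rs %in% 0:5)) {
    stop("reliability scores must be integers in 0..5", call. = FALSE)
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  ann <- setNames(as.integer(annotations$rs),
                  key(annotations$term_a, annotations$term_b))
  hit <- unname(ann[key(pairs$term_a, pairs$term_b)])
  pairs$rs <- ifelse(is.na(hit), pairs$rs, hit)
  pairs
}

#' Write a pair table as TSV
#' @param pairs A pair table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pair_table <- function(pairs, path) {
  readr::write_tsv(tibble::as_tibble(pairs), path)
  invisible(path)
}

#' Scatter of Jaccard index against normalized embedding distance
#'
#' The framework's diagnostic view: closely embedded pairs (small normalized
#' distance) tend to have larger gene-set overlap; the dashed line marks the
#' closest-fraction threshold.
#'
#' @param object A `term_pair_table`.
#' @param fraction Threshold fraction drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot term_pair_table
#' @export
autoplot.term_pair_table <- function(object, fraction = 0.05, ...) {
  thr <- top_fraction_threshold(object$norm_distance, fraction)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$norm_distance, y = .data$jaccard)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "normalized embedding distance", y = "Jaccard index",
                  title = sprintf("Term-pair overlap vs embedding distance (top %.0f%% line)",
                                  100 * fraction))
}
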