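# Independent brute-force oracles used to pin down expected values.

# Upper-tail hypergeometric by exhaustive enumeration of all C(N, size_b)
# draws from a universe with size_a marked successes (N <= 12).
enum_hypergeom <- function(k, size_a, size_b, N) {
  draws <- utils::combn(N, size_b)
  hits <- colSums(draws <= size_a)  # successes are elements 1..size_a
  mean(hits >= k)
}

# Silhouette by direct evaluation of the printed formula.
brute_silhouette <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(factor(labels))
  n <- nrow(points)
  d <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a_i <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b_i <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(vapply(which(labels == cl), function(j) d(i, j), numeric(1)))
    }, numeric(1)))
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

# Davies-Bouldin by direct evaluation of the printed formula.
brute_davies_bouldin <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(factor(labels))
  ks <- sort(unique(labels))
  centroids <- lapply(ks, function(cl) colMeans(points[labels == cl, , drop = FALSE]))
  sigma <- vapply(seq_along(ks), function(ci) {
    idx <- which(labels == ks[ci])
    mean(vapply(idx, function(i) sqrt(sum((points[i, ] - centroids[[ci]])^2)),
                numeric(1)))
  }, numeric(1))
  mean(vapply(seq_along(ks), function(i) {
    max(vapply(setdiff(seq_along(ks), i), function(j) {
      (sigma[i] + sigma[j]) / sqrt(sum((centroids[[i]] - centroids[[j]])^2))
    }, numeric(1)))
  }, numeric(1)))
}

# Minimum spanning-tree weight by enumerating all n^(n-2) labelled spanning
# trees via Pruefer sequences.
enum_mst_weight <- function(dm) {
  n <- nrow(dm)
  prufer_to_edges <- function(seq) {
    degree <- rep(1L, n)
    for (v in seq) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, nrow = n - 1L, ncol = 2L)
    for (i in seq_along(seq)) {
      leaf <- min(which(degree == 1L))
      edges[i, ] <- c(leaf, seq[i])
      degree[leaf] <- degree[leaf] - 1L
      degree[seq[i]] <- degree[seq[i]] - 1L
    }
    edges[n - 1L, ] <- which(degree == 1L)
    edges
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  min(apply(seqs, 1L, function(s) {
    e <- prufer_to_edges(as.integer(s))
    sum(dm[e])
  }))
}

# Shortest-path distances via igraph, used as the d(v,x) oracle.
igraph_distances <- function(graph) {
  g <- igraph::graph_from_edgelist(
    cbind(graph$edges$gene_index, graph$edges$term_index) + 1L,
    directed = FALSE
  )
  igraph::distances(g)
}
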