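test_that("Jaccard index matches its definition on the boundary cases", {
  expect_equal(jaccard_index(c("g1", "g2"), c("g1", "g2")), 1)
  expect_equal(jaccard_index("g1", "g2"), 0)
  expect_equal(jaccard_index(c("a", "b", "c"), c("c", "d")), 0.25)
  expect_error(jaccard_index(character(0), "a"), "non-empty")
})

test_that("Jaccard is symmetric, bounded, and monotone under shared additions", {
  set.seed(42)
  pool <- sprintf("G%03d", 1:50)
  for (i in 1:25) {
    a <- sample(pool, sample(1:20, 1))
    b <- sample(pool, sample(1:20, 1))
    j <- jaccard_index(a, b)
    expect_equal(j, jaccard_index(b, a))
    expect_gte(j, 0)
    expect_lte(j, 1)
    expect_equal(j == 1, setequal(a, b))
    # adding a shared gene never decreases the index
    extra <- "SHARED_NEW"
    expect_gte(jaccard_index(c(a, extra), c(b, extra)), j)
  }
})

test_that("hypergeometric upper tail equals exhaustive enumeration for N <= 12", {
  expect_equal(hypergeometric_pvalue(0, 3, 4, 10), 1)
  # N = 10, both sets of 5, full overlap: 1 / C(10,5) = 1/252
  expect_equal(hypergeometric_pvalue(5, 5, 5, 10), 1 / 252)
  expect_equal(enum_hypergeom(5, 5, 5, 10), 1 / 252)
  # N = 4, sets of 2, overlap >= 1: 5/6 by enumeration
  expect_equal(hypergeometric_pvalue(1, 2, 2, 4), 5 / 6)
  expect_equal(enum_hypergeom(1, 2, 2, 4), 5 / 6)
  set.seed(7)
  for (i in 1:20) {
    N <- sample(4:12, 1)
    sa <- sample(1:N, 1)
    sb <- sample(1:N, 1)
    k <- sample(0:min(sa, sb), 1)
    expect_equal(hypergeometric_pvalue(k, sa, sb, N), enum_hypergeom(k, sa, sb, N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeometric_pvalue(3, 2, 5, 10), "inconsistent")
  expect_error(hypergeometric_pvalue(1, 2, 5, 4), "inconsistent")
})

test_that("pairwise term distances match a brute-force double loop", {
  coll <- generate_collection(synthetic_spec(
    n_modules = 2L, terms_per_module = 5L, pool_size = 8L, genes_per_term = 4L,
    noise_genes_per_term = 0L, background_pool_size = 10L, seed = 2L))
  fit <- embed_collection(coll, small_config(seed = 2L, d = 8L, epochs = 3L))
  dm <- pairwise_term_distances(fit$embedding)
  tv <- term_vectors(fit$embedding)
  expect_equal(dim(dm), c(10L, 10L))
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, 10))
  for (i in 1:10) for (j in 1:10) {
    expect_equal(dm[i, j], sqrt(sum((tv[i, ] - tv[j, ])^2)), tolerance = 1e-12)
  }
  # cosine variant agrees with its definition
  dc <- pairwise_term_distances(fit$embedding, metric = "cosine")
  cosd <- function(x, y) 1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  expect_equal(dc[2, 7], cosd(tv[2, ], tv[7, ]), tolerance = 1e-12)
  # euclidean toy: (0,0) vs (3,4)
  toy <- structure(list(
    vectors = rbind(G1 = c(0, 0), TA = c(0, 0), TB = c(3, 4)),
    d = 2L,
    index = structure(list(gene_to_index = c(G1 = 0L),
                           term_to_index = c(TA = 1L, TB = 2L),
                           m = 1L, n = 2L), class = "node_index"),
    config = NULL), class = "node_embedding")
  expect_equal(pairwise_term_distances(toy)["TA", "TB"], 5)
})

test_that("min-max normalization maps to [0,1] with the constant-input convention", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(7, 7)), c(0, 0))
  set.seed(3)
  x <- rnorm(50)
  nx <- minmax_normalize(x)
  expect_equal(nx[which.min(x)], 0)
  expect_equal(nx[which.max(x)], 1)
  expect_true(all(nx >= 0 & nx <= 1))
})

test_that("top-fraction threshold selects the closest ceiling(f*N) values", {
  expect_equal(top_fraction_threshold(sample(1:100), 0.05), 5)
  x <- runif(30)
  expect_equal(top_fraction_threshold(x, 1), max(x))
  expect_equal(sum(x <= top_fraction_threshold(x, 0.1)), ceiling(0.1 * 30))
  expect_error(top_fraction_threshold(x, 0), "fraction")
  expect_error(top_fraction_threshold(x, 1.2), "fraction")
})

test_that("pair table rows equal independently recomputed statistics", {
  coll <- gs_collection(
    sprintf("T%d", 1:6), "d",
    list(c("A", "B", "C"), c("A", "B", "C"), c("B", "C", "D"),
         c("E", "F"), c("A", "F", "G"), c("H", "B"))
  )
  fit <- embed_collection(coll, small_config(seed = 4L, d = 8L, epochs = 3L))
  pt <- build_pair_table(fit$graph, fit$embedding, coll)
  expect_equal(nrow(pt), choose(6, 2))
  N <- length(unique(unlist(coll$genes)))
  gset <- setNames(coll$genes, coll$term_id)
  dm <- pairwise_term_distances(fit$embedding)
  for (r in seq_len(nrow(pt))) {
    a <- gset[[pt$term_a[r]]]
    b <- gset[[pt$term_b[r]]]
    expect_equal(pt$jaccard[r], jaccard_index(a, b))
    expect_equal(pt$hypergeom_p[r],
                 hypergeometric_pvalue(length(intersect(a, b)),
                                       length(a), length(b), N))
    expect_equal(pt$raw_distance[r], dm[pt$term_a[r], pt$term_b[r]])
  }
  expect_equal(pt$norm_distance, minmax_normalize(pt$raw_distance))
  # identical gene sets: jaccard 1 and minimal p among pairs of those sizes
  ident <- which(pt$term_a == "T1" & pt$term_b == "T2")
  expect_equal(pt$jaccard[ident], 1)
  expect_equal(pt$hypergeom_p[ident], min(pt$hypergeom_p))
  # optional BH adjustment adds a column, off by default
  expect_false("hypergeom_p_adj" %in% names(pt))
  pt_adj <- build_pair_table(fit$graph, fit$embedding, coll, adjust = TRUE)
  expect_equal(pt_adj$hypergeom_p_adj,
               stats::p.adjust(pt_adj$hypergeom_p, method = "BH"))
})

test_that("top_pairs filters at the threshold with ties included", {
  coll <- tiny_collection()
  fit <- embed_collection(coll, small_config(seed = 7L, d = 8L, epochs = 3L))
  pt <- build_pair_table(fit$graph, fit$embedding, coll)
  sub <- top_pairs(pt, 0.2)
  thr <- top_fraction_threshold(pt$norm_distance, 0.2)
  expect_equal(attr(sub, "threshold"), thr)
  expect_equal(nrow(sub), sum(pt$norm_distance <= thr))
  expect_gte(nrow(sub), ceiling(0.2 * nrow(pt)))
})

test_that("reliability-score annotations merge into the pair table", {
  coll <- tiny_collection()
  fit <- embed_collection(coll, small_config(seed = 7L, d = 8L, epochs = 3L))
  pt <- build_pair_table(fit$graph, fit$embedding, coll)
  ann <- tibble::tibble(term_a = pt$term_b[2], term_b = pt$term_a[2], rs = 4L)
  out <- annotate_rs(pt, ann)
  expect_equal(out$rs[2], 4L)
  expect_true(all(is.na(out$rs[-2])))
  expect_error(annotate_rs(pt, tibble::tibble(term_a = "x", term_b = "y", rs = 9L)),
               "0..5")
})
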