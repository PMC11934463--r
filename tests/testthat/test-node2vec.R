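test_that("transition distribution follows the 1/p, 1, 1/q cases and normalizes", {
  g <- path3_graph()
  # previous = GA (0), current = T1 (2), candidates GA and GC
  td <- transition_distribution(g, previous = 0L, current = 2L,
                                config = walk_config(p = 2, q = 0.5))
  expect_equal(td$candidate, c(0L, 1L))
  # weights {1/p = 0.5, 1/q = 2} -> probabilities {0.2, 0.8}
  expect_equal(td$probability, c(0.2, 0.8))
  expect_equal(sum(td$probability), 1)

  # p = q = 1 gives the uniform distribution over neighbors
  td1 <- transition_distribution(g, 0L, 2L, walk_config(p = 1, q = 1))
  expect_equal(td1$probability, c(0.5, 0.5))

  expect_error(transition_distribution(g, 1L, 0L), "not adjacent")
})

test_that("on bipartite graphs the d(v,x)=1 branch is unreachable for x != previous", {
  # exhaustive check against an igraph shortest-path oracle on random graphs
  for (seed in 1:5) {
    coll <- tiny_collection(seed = seed)
    g <- build_graph(coll)
    sp <- igraph_distances(g)
    cfg <- walk_config(p = 3, q = 7)
    for (cur in c(0L, g$index$m, g$index$m + 1L)) {
      for (prev in neighbors(g, cur)) {
        td <- transition_distribution(g, prev, cur, cfg)
        w <- ifelse(td$candidate == prev, 1 / cfg$p, 1 / cfg$q)
        expect_equal(td$probability, w / sum(w))
        others <- td$candidate[td$candidate != prev]
        # same partition as prev: distance 0 or 2, never 1
        expect_true(all(sp[prev + 1L, others + 1L] %in% c(0, 2)))
      }
    }
  }
})

test_that("walk corpus honours the count, adjacency and determinism contracts", {
  coll <- gs_collection(c("T1", "T2"), "d", list(c("G1", "G2"), c("G2", "G3")))
  g <- build_graph(coll)  # |V| = 5
  cfg <- walk_config(walks_per_node = 10L, walk_length = 8L, seed = 4L)
  corpus <- simulate_walks(g, cfg)
  expect_length(corpus, 5L * 10L)
  expect_true(all(lengths(corpus) <= cfg$walk_length + 1L))
  for (wk in corpus) {
    for (i in seq_len(length(wk) - 1L)) {
      expect_true(wk[i + 1L] %in% neighbors(g, wk[i]))
    }
  }
  # each node starts exactly walks_per_node walks
  starts <- vapply(corpus, `[[`, integer(1), 1L)
  expect_equal(unname(table(starts)), rep(10L, 5L), ignore_attr = TRUE)
  expect_identical(unclass(simulate_walks(g, cfg)), unclass(corpus),
                   ignore_attr = TRUE)
})

test_that("simulated second-step frequencies match the transition distribution", {
  g <- path3_graph()
  cfg <- walk_config(p = 2, q = 0.5, walk_length = 2L, walks_per_node = 3000L,
                     seed = 21L)
  corpus <- simulate_walks(g, cfg)
  # walks starting at gene GA (0) are forced to T1 (2); the second step
  # has previous = 0, current = 2
  from_a <- Filter(function(wk) wk[1] == 0L && length(wk) == 3L, corpus)
  third <- vapply(from_a, `[[`, integer(1), 3L)
  freq <- mean(third == 1L)  # GC
  expect_gt(length(from_a), 1000L)
  expect_equal(freq, 0.8, tolerance = 0.05)
})

test_that("small q wanders farther than large q on a long path", {
  n_genes <- 31L
  coll <- gs_collection(
    term_id = sprintf("T%02d", seq_len(n_genes - 1L)),
    description = "chain",
    genes = lapply(seq_len(n_genes - 1L), function(i)
      sprintf("G%02d", c(i, i + 1L)))
  )
  g <- build_graph(coll)
  # position along the path: gene i at 2(i-1), term i at 2i-1
  pos <- integer(g$index$m + g$index$n)
  pos[g$index$gene_to_index + 1L] <- 2L * (seq_len(g$index$m) - 1L)
  pos[g$index$term_to_index + 1L] <- 2L * seq_len(g$index$n) - 1L
  displacement <- function(q) {
    cfg <- walk_config(p = 1, q = q, walk_length = 10L, walks_per_node = 20L,
                       seed = 33L)
    corpus <- simulate_walks(g, cfg)
    mean(vapply(corpus, function(wk)
      abs(pos[wk[length(wk)] + 1L] - pos[wk[1] + 1L]), numeric(1)))
  }
  expect_gt(displacement(0.25), displacement(4))
})

test_that("training returns one finite d-vector per node, deterministically under seed", {
  coll <- tiny_collection()
  g <- build_graph(coll)
  cfg <- small_config(seed = 5L)
  corpus <- simulate_walks(g, cfg)
  emb <- train_embeddings(corpus, g, cfg)
  expect_equal(dim(emb$vectors), c(g$index$m + g$index$n, cfg$dimensions))
  expect_true(all(is.finite(emb$vectors)))
  expect_identical(train_embeddings(corpus, g, cfg)$vectors, emb$vectors)
  cfg2 <- small_config(seed = 6L)
  emb2 <- train_embeddings(simulate_walks(g, cfg2), g, cfg2)
  expect_false(identical(emb2$vectors, emb$vectors))
  # corpus referencing an unknown node is rejected
  bad <- structure(list(c(0L, 9999L)), class = "walk_corpus")
  expect_error(train_embeddings(bad, g, cfg), "unknown node")
})

test_that("embeddings separate two gene communities joined by a bridge", {
  # two dense bipartite blocks sharing a single bridge gene
  ga <- sprintf("A%d", 1:6); gb <- sprintf("B%d", 1:6)
  coll <- gs_collection(
    term_id = c(sprintf("TA%d", 1:4), sprintf("TB%d", 1:4)),
    description = "block",
    genes = c(
      lapply(1:4, function(i) ga),
      lapply(1:4, function(i) if (i == 1) c(gb, ga[1]) else gb)
    )
  )
  g <- build_graph(coll)
  cfg <- small_config(seed = 2L, epochs = 15L)
  emb <- train_embeddings(simulate_walks(g, cfg), g, cfg)
  v <- emb$vectors
  cos <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  block_a <- c(ga, sprintf("TA%d", 1:4))
  block_b <- c(gb, sprintf("TB%d", 1:4))
  pair_mean <- function(s1, s2) {
    mean(apply(expand.grid(s1, s2, stringsAsFactors = FALSE), 1L,
               function(p) if (p[1] == p[2]) NA else cos(v[p[1], ], v[p[2], ])),
         na.rm = TRUE)
  }
  intra <- mean(c(pair_mean(block_a, block_a), pair_mean(block_b, block_b)))
  inter <- pair_mean(block_a, block_b)
  expect_gt(intra, inter)
})

test_that("embed_collection composes the stages and is seed-deterministic", {
  coll <- tiny_collection()
  cfg <- small_config(seed = 12L)
  fit <- embed_collection(coll, cfg)
  expect_equal(nrow(fit$embedding$vectors),
               fit$graph$index$m + fit$graph$index$n)
  fit2 <- embed_collection(coll, cfg)
  expect_identical(fit$embedding$vectors, fit2$embedding$vectors)
  td <- tidy(fit$embedding)
  expect_equal(nrow(td), nrow(fit$embedding$vectors))
  expect_equal(sum(td$partition == "term"), nrow(coll))
})

test_that("embedding and config serialization round-trip", {
  coll <- tiny_collection()
  cfg <- small_config(seed = 8L)
  fit <- embed_collection(coll, cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_embeddings(fit$embedding, path)
  back <- read_embeddings(path)
  expect_equal(unname(back$vectors), unname(fit$embedding$vectors),
               tolerance = 1e-6)
  expect_equal(back$index$term_to_index, fit$graph$index$term_to_index)

  cpath <- withr::local_tempfile(fileext = ".txt")
  write_walk_config(cfg, cpath)
  expect_equal(read_walk_config(cpath), cfg)
})

test_that("configuration invariants are enforced", {
  expect_error(walk_config(p = 0))
  expect_error(walk_config(q = -1))
  expect_error(walk_config(walk_length = 0))
  expect_error(walk_config(dimensions = 0))
  grid <- hyperparameter_grid()
  cfg <- as_walk_config(grid[1234, ])
  expect_s3_class(cfg, "walk_config")
  expect_equal(cfg$epochs, 40L)
})
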