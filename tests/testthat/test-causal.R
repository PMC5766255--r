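test_that("chain SEM yields the chain skeleton without a shortcut edge", {
  sem <- simulate_sem(data.frame(from = c("X", "Y"), to = c("Y", "Z"),
                                 weight = 1), 2000, seed = 1)
  g <- greedy_search(sem$data)
  expect_identical(skeleton_of(g), c("X|Y", "Y|Z"))
})

test_that("collider edges are compelled into the collider", {
  sem <- simulate_sem(data.frame(from = c("X", "Y"), to = c("Z", "Z"),
                                 weight = 1), 5000, seed = 2)
  g <- greedy_search(sem$data)
  expect_identical(skeleton_of(g), c("X|Z", "Y|Z"))
  dir <- g$edges[g$edges$orientation == "directed", ]
  expect_setequal(dir$to, "Z")
  expect_setequal(dir$from, c("X", "Y"))
})

test_that("independent columns give an empty graph; constants are rejected", {
  set.seed(3)
  x <- matrix(rnorm(2000 * 5), 2000, 5,
              dimnames = list(NULL, paste0("V", 1:5)))
  expect_equal(nrow(greedy_search(x)$edges), 0L)
  x[, 2] <- 1
  expect_error(greedy_search(x), "V2")
  expect_error(greedy_search(cbind(x[1:10, 1, drop = FALSE], NA)),
               "complete")
})

test_that("directed part of the pattern is acyclic and the score beats empty", {
  set.seed(4)
  dag <- data.frame(from = c("A", "A", "B", "C"),
                    to = c("B", "C", "D", "D"),
                    weight = c(1, -0.8, 0.7, 1.2))
  sem <- simulate_sem(dag, 1500, seed = 5, nodes = LETTERS[1:5])
  g <- greedy_search(sem$data)
  dirpart <- g$edges[g$edges$orientation == "directed", ]
  if (nrow(dirpart)) {
    ig <- igraph::graph_from_data_frame(dirpart[, c("from", "to")],
                                        directed = TRUE)
    expect_true(igraph::is_dag(ig))
  }
  n <- nrow(sem$data)
  C <- crossprod(scale(sem$data, scale = FALSE))
  empty_score <- sum(vapply(seq_len(ncol(C)), function(v)
    -(n / 2) * log(C[v, v] / n) - 4 * log(n) / 2, 0))
  expect_gte(g$score, empty_score)
})

test_that("the learned skeleton is invariant to per-column standardization", {
  set.seed(6)
  dag <- data.frame(from = c("A", "B", "C"), to = c("B", "C", "D"),
                    weight = c(1.5, -1, 0.8))
  sem <- simulate_sem(dag, 1000, seed = 7)
  g1 <- greedy_search(sem$data)
  g2 <- greedy_search(scale(sem$data))
  expect_identical(skeleton_of(g1), skeleton_of(g2))
})

test_that("bootstrap_ensemble: determinism, strong-edge and null frequencies", {
  sem <- simulate_sem(data.frame(from = "A", to = "B", weight = 2),
                      1000, noise_sd = 0.5, seed = 8,
                      nodes = c("A", "B", "C", "D"))
  e1 <- bootstrap_ensemble(sem$data, M = 50, seed = 9)
  e2 <- bootstrap_ensemble(sem$data, M = 50, seed = 9)
  expect_identical(e1$edge_freq, e2$edge_freq)
  strong <- e1$edge_freq[e1$edge_freq$a == "A" & e1$edge_freq$b == "B", ]
  expect_gte(strong$freq_any, 0.9)
  null_edges <- e1$edge_freq[!(e1$edge_freq$a == "A" &
                                 e1$edge_freq$b == "B"), ]
  if (nrow(null_edges)) expect_lte(max(null_edges$freq_any), 0.2)
  expect_gte(e1$avg_connectivity, 1)
})

test_that("centralities: star, path and isolated-node closed forms", {
  star <- structure(list(
    nodes = c("hub", paste0("L", 1:5)),
    edges = data.frame(from = "hub", to = paste0("L", 1:5),
                       orientation = "directed")), class = "causal_graph")
  cs <- centralities(star)
  expect_equal(cs$out_degree[cs$node == "hub"], 5L)
  expect_equal(cs$in_degree[cs$node == "hub"], 0L)
  expect_true(all(cs$in_degree[cs$node != "hub"] == 1L))

  path <- structure(list(
    nodes = c("A", "B", "C"),
    edges = data.frame(from = c("A", "B"), to = c("B", "C"),
                       orientation = "directed")), class = "causal_graph")
  cp <- centralities(path)
  expect_equal(cp$betweenness, c(0, 1, 0))

  iso <- structure(list(
    nodes = c("A", "B", "C"),
    edges = data.frame(from = "A", to = "B", orientation = "directed")),
    class = "causal_graph")
  ci <- centralities(iso)
  expect_equal(ci$subgraph_centrality[ci$node == "C"], 1, tolerance = 1e-12)
  # A-B pair: diag of expm of 2x2 adjacency = cosh(1)
  expect_equal(ci$subgraph_centrality[ci$node == "A"], cosh(1),
               tolerance = 1e-10)
})

test_that("causal_neighborhood: trivial cuts and tissue-specific correlations", {
  g <- structure(list(
    nodes = c("A", "B", "C", "D"),
    edges = data.frame(from = c("A", "B"), to = c("B", "C"),
                       orientation = "directed")), class = "causal_graph")
  # target with no neighbours
  nb0 <- causal_neighborhood(g, "D")
  expect_identical(nb0$nodes, "D")
  expect_equal(nrow(nb0$edges), 0L)
  # neighbourhood of everything is the full graph
  nball <- causal_neighborhood(g, g$nodes)
  expect_equal(nrow(nball$edges), 2L)
  expect_error(causal_neighborhood(g, "ZZ"), "unknown target")

  # planted opposite-sign correlation per tissue
  set.seed(11)
  n <- 60
  tis <- rep(c("t1", "t2"), each = n)
  a <- rnorm(2 * n)
  b <- c(0.9 * a[1:n], -0.9 * a[(n + 1):(2 * n)]) +
    rnorm(2 * n, 0, sqrt(1 - 0.81))
  dat <- cbind(A = a, B = b, C = rnorm(2 * n), D = rnorm(2 * n))
  nb <- causal_neighborhood(g, "A", data = dat, tissues = tis)
  ab <- nb$tissue_cor[nb$tissue_cor$from == "A" & nb$tissue_cor$to == "B", ]
  expect_gt(ab$r[ab$tissue == "t1"], 0.5)
  expect_lt(ab$r[ab$tissue == "t2"], -0.5)
})

test_that("compare_ensembles: identity, affine scaling, disjoint nodes", {
  ef <- data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"),
                   freq_any = c(0.9, 0.4, 0.1),
                   freq_a_to_b = 0, freq_b_to_a = 0, freq_undirected = 0)
  eA <- structure(list(M = 10, n_success = 10, edge_freq = ef,
                       avg_connectivity = 1.4, nodes = c("A", "B", "C")),
                  class = "bootstrap_ensemble")
  expect_equal(compare_ensembles(eA, eA)$pearson, 1, tolerance = 1e-12)
  eB <- eA
  eB$edge_freq$freq_any <- 0.5 * ef$freq_any
  cmp <- compare_ensembles(eA, eB)
  expect_equal(cmp$pearson, 1, tolerance = 1e-12)
  expect_equal(cmp$spearman, 1, tolerance = 1e-12)
  eC <- eA; eC$nodes <- c("X", "Y")
  expect_error(compare_ensembles(eA, eC), "no shared nodes")
})

test_that("ensembles from independent SEMs show no positive association", {
  # Note: over the union of detected edges (absent edges counted as 0),
  # independent ensembles with disjoint supports are *negatively*
  # correlated by construction (two disjoint binary supports give exactly
  # -1), so the sound null property is the absence of positive
  # association, not correlation near zero.
  mk <- function(seed) {
    nodes <- sprintf("N%02d", 1:12)
    set.seed(seed * 17)
    pairs <- t(combn(nodes, 2))
    sel <- sample(nrow(pairs), 10)
    dag <- data.frame(from = pairs[sel, 1], to = pairs[sel, 2],
                      weight = 0.25)
    simulate_sem(dag, 120, seed = seed, nodes = nodes)$data
  }
  eA <- bootstrap_ensemble(mk(1), M = 25, seed = 3)
  eB <- bootstrap_ensemble(mk(2), M = 25, seed = 4)
  expect_lt(compare_ensembles(eA, eB)$pearson, 0.3)
  # while an ensemble against itself is perfectly correlated
  expect_equal(compare_ensembles(eA, eA)$pearson, 1, tolerance = 1e-12)
})
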