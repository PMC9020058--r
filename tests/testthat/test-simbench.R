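test_that("network generation is deterministic and well-formed", {
  g1 <- generate_network(50, 2, seed = 1)
  g2 <- generate_network(50, 2, seed = 1)
  expect_equal(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  expect_false(identical(igraph::as_edgelist(g1),
                         igraph::as_edgelist(generate_network(50, 2, seed = 2))))
  expect_false(any(igraph::which_loop(g1)))
  expect_false(igraph::any_multiple(g1))
  expect_true(max(igraph::degree(g1, mode = "out")) >= 1)
  g_min <- generate_network(2, 1, seed = 3)
  expect_equal(igraph::vcount(g_min), 2L)
  expect_error(generate_network(1, 2), "n_nodes")
})

test_that("planted subgraphs grow along out-edges from the root", {
  path <- deregnet_network(data.frame(source = c("A", "B", "C"),
                                      target = c("B", "C", "D")))
  set.seed(341)
  for (i in 1:20) {
    res <- simulate_true_subgraph(path, 3, 3)
    expect_true(paste(res$nodes, collapse = ",") %in%
                  c("A,B,C", "B,C,D"))  # only two growth trajectories exist
    expect_true(res$root %in% res$nodes)
  }
  single <- simulate_true_subgraph(path, 1, 1)
  expect_length(single$nodes, 1L)

  star <- deregnet_network(data.frame(source = rep("hub", 4),
                                      target = paste0("leaf", 1:4)))
  for (i in 1:10) {
    res <- simulate_true_subgraph(star, 3, 3)
    expect_true("hub" %in% res$nodes)  # leaf roots cannot grow: restarts
    expect_equal(res$root, "hub")
    expect_length(res$nodes, 3L)
  }
  lonely <- deregnet_network(data.frame(source = "A", target = "B"),
                             nodes = c("A", "B", "C"))
  expect_error(simulate_true_subgraph(lonely, 3, 3, max_retries = 5),
               "too sparse")
})

test_that("planted subgraphs are root-connected within themselves", {
  set.seed(342)
  g <- generate_network(60, 2, seed = 9)
  for (i in 1:10) {
    res <- simulate_true_subgraph(g, 4, 8)
    sub <- igraph::induced_subgraph(g, res$nodes)
    reach <- names(igraph::subcomponent(sub, res$root, mode = "out"))
    expect_setequal(reach, res$nodes)
  }
})

test_that("score simulation follows the two-rate Bernoulli model", {
  g <- generate_network(30, 2, seed = 5)
  ids <- igraph::V(g)$name
  set.seed(343)
  exact <- simulate_scores(g, ids[1:5], p = 0, p_prime = 1)
  expect_equal(unname(exact[ids[1:5]]), rep(1, 5))
  expect_equal(sum(exact), 5)

  # concentration of the inside rate on a large planted set
  big <- generate_network(4000, 2, seed = 6)
  inside <- igraph::V(big)$name[1:2000]
  s <- simulate_scores(big, inside, p = 0.05, p_prime = 0.7)
  expect_lt(abs(mean(s[inside]) - 0.7), 3 * sqrt(0.7 * 0.3 / 2000))
  expect_true(all(s %in% c(0, 1)))
})

test_that("recovery metrics reproduce the worked confusion example", {
  m <- evaluate_subgraph(c("b", "c", "d"), c("a", "b", "c"), 10)
  expect_equal(m$tp, 2)
  expect_equal(m$fp, 1)
  expect_equal(m$fn, 1)
  expect_equal(m$tn, 6)
  expect_equal(m$tpr, 2 / 3)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$jaccard, 0.5)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$mcc, 11 / 21)
  expect_equal(m$size_efficiency, 1)

  perfect <- evaluate_subgraph(letters[1:3], letters[1:3], 8)
  expect_equal(unlist(perfect[c("tpr", "precision", "f1", "jaccard", "mcc",
                                "size_efficiency")]),
               c(tpr = 1, precision = 1, f1 = 1, jaccard = 1, mcc = 1,
                 size_efficiency = 1))

  disjoint <- evaluate_subgraph(c("x", "y"), letters[1:3], 10)
  expect_equal(unlist(disjoint[c("tpr", "precision", "f1", "jaccard")]),
               c(tpr = 0, precision = 0, f1 = 0, jaccard = 0))
  expect_equal(disjoint$size_efficiency, 2 / 3)
  expect_error(evaluate_subgraph("a", character(), 5), "non-empty")
})

test_that("metric identities hold on random confusion configurations", {
  set.seed(344)
  for (i in 1:25) {
    u <- sprintf("u%02d", 1:12)
    truth <- sample(u, sample(1:8, 1))
    pred <- sample(u, sample(0:10, 1))
    m <- evaluate_subgraph(pred, truth, length(u))
    expect_equal(m$tp + m$fp + m$fn + m$tn, length(u))
    expect_true(m$mcc >= -1 && m$mcc <= 1)
    if (m$precision > 0 && m$tpr > 0) {
      expect_equal(m$f1, 2 / (1 / m$precision + 1 / m$tpr))
    }
  }
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  u <- letters[1:10]
  dereg <- u[1:5]
  expect_equal(hypergeom_enrichment(u[1:3], dereg, u), 10 / 120)
  expect_equal(hypergeom_enrichment(character(), dereg, u), 1)
  expect_equal(hypergeom_enrichment(u[1:3], u, u), 1)
  expect_error(hypergeom_enrichment("a", "a", character()), "empty universe")

  # exact tail by enumerating all draws of |set| from |U|
  set.seed(345)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    u <- sprintf("g%d", 1:n)
    dereg <- sample(u, sample(1:(n - 1), 1))
    k <- sample(1:(n - 1), 1)
    gset <- sample(u, k)
    obs <- length(intersect(gset, dereg))
    draws <- utils::combn(u, k, simplify = FALSE)
    exact <- mean(vapply(draws, function(d) {
      length(intersect(d, dereg)) >= obs
    }, logical(1)))
    expect_equal(hypergeom_enrichment(gset, dereg, u), exact,
                 tolerance = 1e-12)
  }
})

test_that("benchmark runs are reproducible and recover noiseless truths", {
  g <- generate_network(40, 2, seed = 13)
  cfg <- simulation_config(p = 1e-9, p_prime = 1, true_size_min = 3,
                           true_size_max = 5, k_min = 2, k_max = 6,
                           n_instances = 3, seed = 5)
  r1 <- suppressMessages(run_benchmark(g, cfg))
  r2 <- suppressMessages(run_benchmark(g, cfg))
  drop_rt <- function(x) dplyr::select(tibble::as_tibble(x), -"runtime")
  expect_equal(drop_rt(r1), drop_rt(r2))
  expect_equal(nrow(r1), 6L)
  expect_setequal(unique(r1$algorithm), c("deregnet", "fixed_size_union"))
  # with indicator scores the planted subgraph is the unique average-1
  # optimum of maximal extent, so recovery is perfect
  drn <- r1[r1$algorithm == "deregnet", ]
  expect_equal(drn$fp, rep(0L, nrow(drn)))
  expect_equal(drn$fn, rep(0L, nrow(drn)))
  expect_equal(drn$mcc, rep(1, nrow(drn)))

  empty <- run_benchmark(g, simulation_config(n_instances = 0))
  expect_equal(nrow(empty), 0L)
})

test_that("benchmark config validates its probability ordering", {
  expect_error(simulation_config(p = 0.5, p_prime = 0.5), "p < p_prime")
  expect_error(simulation_config(p = 0.9, p_prime = 0.1), "p < p_prime")
})

test_that("benchmark results have an autoplot method", {
  g <- generate_network(30, 2, seed = 21)
  cfg <- simulation_config(p = 0.01, p_prime = 1, true_size_min = 3,
                           true_size_max = 4, k_min = 2, k_max = 5,
                           n_instances = 1, seed = 3)
  res <- suppressMessages(run_benchmark(g, cfg))
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})
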