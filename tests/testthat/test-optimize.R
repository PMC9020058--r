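test_that("check_feasible validates the worked constraint examples", {
  g1 <- deregnet_network(data.frame(source = c("R1", "A"),
                                    target = c("A", "B")))
  inst1 <- deregnet_instance(g1, c(R1 = 1, A = 1, B = 1), receptors = "R1",
                             terminals = "B", k_min = 2, k_max = 5)
  chk <- check_feasible(inst1, c("R1", "A", "B"), "R1")
  expect_true(chk$feasible)
  expect_length(chk$violated, 0L)

  # a 2-cycle with no incoming selected edge violates the component rule
  g2 <- deregnet_network(data.frame(source = c("R1", "B", "C"),
                                    target = c("A", "C", "B")))
  inst2 <- deregnet_instance(g2, stats::setNames(rep(1, 4), c("R1", "A", "B", "C")),
                             k_min = 2, k_max = 5)
  chk2 <- check_feasible(inst2, c("R1", "B", "C"), "R1")
  expect_false(chk2$feasible)
  expect_true("1f" %in% chk2$violated)
  expect_false("1e" %in% chk2$violated)  # every node has an in-neighbor

  # a node with neither root flag nor selected in-neighbor
  g3 <- deregnet_network(data.frame(source = c("A", "C"),
                                    target = c("B", "D")))
  inst3 <- deregnet_instance(g3, stats::setNames(rep(1, 4), c("A", "B", "C", "D")),
                             k_min = 2, k_max = 5)
  chk3 <- check_feasible(inst3, c("A", "B", "C"), "A")
  expect_false(chk3$feasible)
  expect_true("1e" %in% chk3$violated)
  expect_error(check_feasible(inst3, "A", "Z"), "single network node")
})

test_that("component separation returns exactly the violating cycles", {
  g <- deregnet_network(data.frame(source = c("R1", "B", "C"),
                                   target = c("A", "C", "B")))
  inst <- deregnet_instance(g, stats::setNames(rep(1, 4), c("R1", "A", "B", "C")),
                            k_min = 2, k_max = 4)
  expect_equal(separate_scc_violations(inst, c("R1", "B", "C"), "R1"),
               list(c("B", "C")))

  g2 <- deregnet_network(data.frame(source = c("R1", "A", "B", "C"),
                                    target = c("A", "B", "C", "B")))
  inst2 <- deregnet_instance(g2, stats::setNames(rep(1, 4), c("R1", "A", "B", "C")),
                             k_min = 2, k_max = 4)
  expect_equal(separate_scc_violations(inst2, c("R1", "A", "B", "C"), "R1"),
               list())

  # acyclic selections never violate
  g3 <- deregnet_network(data.frame(source = c("A", "B"), target = c("B", "C")))
  inst3 <- deregnet_instance(g3, c(A = 1, B = 1, C = 1), k_min = 2, k_max = 3)
  expect_equal(separate_scc_violations(inst3, c("A", "B", "C"), "A"), list())
})

test_that("parametric subproblem matches enumeration at lambda = 0 and 1", {
  inst <- triangle_instance(scores = c(A = 1, B = 0.5, C = 1))
  # enumeration oracle over all feasible sets
  feas <- enumerate_feasible_sets(inst)
  s <- inst$score
  par_opt <- function(lambda) {
    vals <- vapply(feas, function(S) sum(s[S]) - lambda * length(S), 0)
    max(vals)
  }
  r0 <- solve_parametric(inst, 0)
  expect_equal(r0$value, par_opt(0))
  expect_equal(r0$value, 2.5)
  expect_setequal(r0$nodes, c("A", "B", "C"))
  expect_equal(r0$root, "A")

  r1 <- solve_parametric(inst, 1)
  expect_equal(r1$value, par_opt(1))
  expect_equal(r1$value, 0)
  expect_setequal(r1$nodes, c("A", "C"))

  inst_ex <- deregnet_instance(triangle_graph(), c(A = 1, B = 0, C = 1),
                               exclude = c("A", "B", "C"), k_min = 1,
                               k_max = 3)
  expect_error(solve_parametric(inst_ex, 0), class = "deregnet_infeasible")
})

test_that("fractional solve finds the optimal average subgraph", {
  sol <- deregnet_solve(triangle_instance())
  expect_setequal(sol$nodes, c("A", "C"))
  expect_equal(sol$objective, 1)
  expect_true(sol$converged)
  expect_equal(sol$objective, sol$total_score / length(sol$nodes))

  sol3 <- deregnet_solve(triangle_instance(k_min = 3))
  expect_setequal(sol3$nodes, c("A", "B", "C"))
  expect_equal(sol3$objective, 2 / 3)

  g1 <- deregnet_network(data.frame(source = character(),
                                    target = character()), nodes = "A")
  inst1 <- deregnet_instance(g1, c(A = 5), receptors = "A", k_min = 1,
                             k_max = 1)
  sol1 <- deregnet_solve(inst1)
  expect_equal(sol1$nodes, "A")
  expect_equal(sol1$objective, 5)
})

test_that("fixed-size solves maximize total score at exact size", {
  g <- triangle_graph()
  s <- c(A = 1, B = 0, C = 1)
  s2 <- solve_fixed_size(g, s, 2, receptors = "A", terminals = "C")
  expect_setequal(s2$nodes, c("A", "C"))
  expect_equal(s2$total_score, 2)
  s3 <- solve_fixed_size(g, s, 3, receptors = "A", terminals = "C")
  expect_setequal(s3$nodes, c("A", "B", "C"))
  expect_equal(s3$total_score, 2)
  expect_error(solve_fixed_size(g, s, 1, receptors = "A", terminals = "C"),
               class = "deregnet_infeasible")
})

test_that("union over sizes accumulates fixed-size optima", {
  g <- triangle_graph()
  s <- c(A = 1, B = 0, C = 1)
  expect_setequal(solve_union_over_sizes(g, s, 2, 3, receptors = "A",
                                         terminals = "C"),
                  c("A", "B", "C"))
  expect_equal(solve_union_over_sizes(g, s, 2, 2, receptors = "A",
                                      terminals = "C"),
               solve_fixed_size(g, s, 2, receptors = "A",
                                terminals = "C")$nodes)
  path <- deregnet_network(data.frame(source = c("R1", "A"),
                                      target = c("A", "B")))
  expect_setequal(
    solve_union_over_sizes(path, c(R1 = 1, A = 1, B = 1), 3, 3,
                           receptors = "R1", terminals = "B"),
    c("R1", "A", "B"))
})

test_that("suboptimal enumeration ranks solutions by no-good cuts", {
  inst <- triangle_instance()
  sols <- solve_suboptimal(inst, n = 1)
  expect_length(sols, 2L)
  expect_equal(vapply(sols, `[[`, 0L, "rank"), c(0L, 1L))
  expect_setequal(sols[[1]]$nodes, c("A", "C"))
  expect_equal(sols[[1]]$objective, 1)
  expect_setequal(sols[[2]]$nodes, c("A", "B", "C"))
  expect_equal(sols[[2]]$objective, 2 / 3)
  # objectives non-increasing
  expect_true(all(diff(vapply(sols, `[[`, 0, "objective")) <= 1e-12))

  expect_length(solve_suboptimal(inst, n = 0), 1L)
  # feasible pool has exactly two sets; asking for more returns both
  expect_length(solve_suboptimal(inst, n = 5), 2L)
})

test_that("union summary counts node occurrences over solutions", {
  inst <- triangle_instance()
  sols <- solve_suboptimal(inst, n = 1)
  um <- union_summary(sols, triangle_graph())
  expect_setequal(igraph::V(um)$name, c("A", "B", "C"))
  freq <- stats::setNames(igraph::V(um)$frequency, igraph::V(um)$name)
  expect_equal(freq[c("A", "B", "C")], c(A = 2L, B = 1L, C = 2L))
  um1 <- union_summary(sols[[1]], triangle_graph())
  expect_true(all(igraph::V(um1)$frequency == 1L))

  pair <- deregnet_network(data.frame(source = character(),
                                      target = character()),
                           nodes = c("A", "B"))
  fake <- function(nodes) {
    inst <- deregnet_instance(pair, c(A = 1, B = 1), k_min = 1, k_max = 2)
    deregnet:::new_solution(nodes, nodes[1], 1, 1, 0L, TRUE, numeric(0), inst)
  }
  um2 <- union_summary(list(fake("A"), fake("B")), pair)
  expect_equal(igraph::gsize(um2), 0L)
  expect_setequal(igraph::V(um2)$name, c("A", "B"))
})

test_that("brute-force oracle agrees with the solver on the toy instance", {
  inst <- triangle_instance()
  bf <- brute_force_optimal(inst)
  expect_setequal(bf$nodes, c("A", "C"))
  expect_equal(bf$objective, 1)
  expect_equal(bf$objective, deregnet_solve(inst)$objective)

  whole <- triangle_instance(k_min = 3, k_max = 3)
  expect_setequal(brute_force_optimal(whole)$nodes, c("A", "B", "C"))

  inst_ex <- deregnet_instance(triangle_graph(), c(A = 1, B = 0, C = 1),
                               exclude = c("A", "B", "C"), k_min = 1,
                               k_max = 3)
  expect_error(brute_force_optimal(inst_ex), class = "deregnet_infeasible")
  big <- generate_network(20, 2, seed = 1)
  inst_big <- deregnet_instance(big, stats::setNames(rep(1, 20), igraph::V(big)$name),
                                k_min = 2, k_max = 3)
  expect_error(brute_force_optimal(inst_big), "enumeration cap")
})

test_that("objective shifts by a constant added to all scores", {
  set.seed(311)
  for (i in 1:10) {
    inst <- random_small_instance(senses = "maximize", absolutes = FALSE)
    base <- tryCatch(deregnet_solve(inst),
                     deregnet_infeasible = function(e) NULL)
    if (is.null(base)) next
    shifted <- inst
    shifted$score <- inst$score + 3.25
    sol <- deregnet_solve(shifted)
    expect_equal(sol$objective, base$objective + 3.25, tolerance = 1e-9)
    expect_setequal(sol$nodes, base$nodes)
  }
})

test_that("reachability equals the in-neighbor plus component conditions", {
  set.seed(312)
  for (i in 1:25) {
    g <- random_digraph(sample(4:9, 1L))
    ids <- igraph::V(g)$name
    inst <- deregnet_instance(g, stats::setNames(rep(1, length(ids)), ids),
                              k_min = 1, k_max = length(ids))
    S <- sample(ids, sample(1:length(ids), 1L))
    root <- sample(S, 1L)
    chk <- check_feasible(inst, S, root)
    bfs_ok <- all(S %in% names(igraph::subcomponent(
      igraph::induced_subgraph(g, S), root, mode = "out")))
    cond_ok <- !any(c("1e", "1f", "reachability") %in% chk$violated)
    expect_equal(cond_ok, bfs_ok)
    # separation agrees: no violating component iff reachable or 1e-only
    if (bfs_ok) {
      expect_length(separate_scc_violations(inst, S, root), 0L)
    }
  }
})

test_that("solutions serialize to GraphML plus JSON sidecar", {
  inst <- triangle_instance()
  sol <- deregnet_solve(inst)
  prefix <- file.path(withr::local_tempdir(), "sol")
  paths <- write_solution(sol, triangle_graph(), prefix)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(js$objective, 1)
  expect_setequal(js$nodes, c("A", "C"))
})

test_that("solutions expose tidy, glance and autoplot views", {
  inst <- triangle_instance()
  sol <- deregnet_solve(inst)
  td <- generics::tidy(sol)
  expect_equal(td$node, c("A", "C"))
  expect_equal(td$is_root, c(TRUE, FALSE))
  gl <- generics::glance(sol)
  expect_equal(gl$objective, 1)
  expect_equal(gl$n_nodes, 2L)
  expect_s3_class(ggplot2::autoplot(sol, triangle_graph()), "ggplot")
})
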