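new_solution <- function(nodes, root, objective, total_score, rank,
                         converged, lambdas, instance,
                         iterations = NA_integer_, gap = NA_real_) {
  structure(
    list(nodes = sort(nodes), root = root, objective = objective,
         total_score = total_score, rank = rank, converged = converged,
         lambdas = lambdas, iterations = iterations, gap = gap,
         k_min = instance$k_min, k_max = instance$k_max,
         sense = instance$sense, mode = instance$mode,
         score = instance$score[sort(nodes)]),
    class = "deregnet_solution"
  )
}

#' @export
print.deregnet_solution <- function(x, ...) {
  cat(sprintf(
    "<deregnet_solution> rank %d | %d nodes | root %s | avg score %.6g%s\n",
    x$rank, length(x$nodes), x$root, x$objective,
    if (isTRUE(x$converged)) "" else " (not converged)"))
  cat("  nodes:", paste(x$nodes, collapse = " "), "\n")
  invisible(x)
}

# Shared backend call. `instance` must already be in effective (forward,
# non-absolute) form. Maximizes sum(w[S]) over feasible S.
core_call <- function(instance, w, settings, cuts, prefer_larger = FALSE) {
  nodes <- names(instance$score)
  idx <- stats::setNames(seq_along(nodes) - 1L, nodes)
  el <- igraph::as_edgelist(instance$graph)
  roots <- if (length(instance$receptors) > 0L) instance$receptors else nodes
  roots <- setdiff(roots, instance$exclude)
  if (length(roots) == 0L) infeasible_error("no admissible root")
  excluded <- nodes %in% instance$exclude
  terminal <- nodes %in% instance$terminals
  cuts_idx <- lapply(cuts, function(cc) unname(idx[as.character(cc)]))
  res <- drn_solve_core(
    n = length(nodes),
    edge_from = unname(idx[el[, 1L]]), edge_to = unname(idx[el[, 2L]]),
    weights = unname(w[nodes]), roots = unname(idx[roots]),
    excluded = excluded, include_idx = unname(idx[instance$include]),
    terminal = terminal,
    enforce_terminal = length(instance$terminals) > 0L,
    kmin = instance$k_min, kmax = instance$k_max, cuts = cuts_idx,
    time_limit = settings$time_limit, node_limit = settings$node_limit,
    prefer_larger = prefer_larger
  )
  res$nodes <- sort(nodes[res$set + 1L])
  res$root_name <- if (res$root >= 0L) nodes[res$root + 1L] else NA_character_
  res
}

# Internal parametric solve on an effective instance; returns nodes, root,
# value (in the instance's sense) or signals infeasible/timeout.
parametric_core <- function(instance, lambda, settings, cuts) {
  maximize <- instance$sense == "maximize"
  w <- if (maximize) instance$score - lambda else lambda - instance$score
  res <- core_call(instance, w, settings, cuts, prefer_larger = TRUE)
  if (!res$feasible) {
    if (res$hit_limit) timeout_error(NULL) else infeasible_error()
  }
  if (res$hit_limit) {
    timeout_error(incumbent = list(nodes = res$nodes, root = res$root_name,
                                   value = if (maximize) res$value else -res$value))
  }
  verify_emitted(instance, res$nodes, res$root_name)
  list(nodes = res$nodes, root = res$root_name,
       value = if (maximize) res$value else -res$value)
}

# Every emitted solution is verified post hoc: full constraint check plus
# an empty component-violation list.
verify_emitted <- function(instance, nodes, root) {
  chk <- check_feasible(instance, nodes, root, tags = TRUE)
  if (!chk$feasible || length(separate_scc_violations(instance, nodes, root)) > 0L) {
    stop("internal solver error: emitted solution failed verification (",
         paste(chk$violated, collapse = ","), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Solve the parametric (non-fractional) subproblem
#'
#' Solves `max s^T x - lambda * e^T x` (or the mirrored minimization) over
#' the instance's feasible subgraphs plus any extra no-good cuts. This is
#' the subproblem iterated by the Dinkelbach scheme in
#' [deregnet_solve()]. The returned value is `s^T x* - lambda * e^T x*`.
#'
#' @param instance A [deregnet_instance()].
#' @param lambda The current ratio parameter.
#' @param settings A [solver_settings()].
#' @param cuts List of character vectors; each listed node set is excluded
#'   as an exact solution (a no-good cut).
#' @return A list with `nodes`, `root` and `value`.
#' @export
solve_parametric <- function(instance, lambda, settings = solver_settings(),
                             cuts = list()) {
  stopifnot(inherits(instance, "deregnet_instance"))
  parametric_core(effective_instance(instance), lambda, settings, cuts)
}

# Average score of a greedy feasible subgraph grown breadth-first from the
# best-scoring admissible root, used to initialize the ratio parameter.
# Falls back to the worst single-node score, which is always a valid bound.
greedy_lambda0 <- function(instance, cuts) {
  maximize <- instance$sense == "maximize"
  fallback <- if (maximize) min(instance$score) else max(instance$score)
  roots <- if (length(instance$receptors) > 0L) instance$receptors
           else names(instance$score)
  roots <- setdiff(roots, instance$exclude)
  if (length(roots) == 0L) return(fallback)
  roots <- sort(roots)
  root <- roots[order(if (maximize) -instance$score[roots]
                      else instance$score[roots])][1L]
  sel <- root
  queue <- root
  head <- 1L
  while (length(sel) < instance$k_min && head <= length(queue)) {
    v <- queue[head]
    head <- head + 1L
    nb <- setdiff(instance$out_adj[[v]], c(sel, instance$exclude))
    for (u in nb) {
      if (length(sel) >= instance$k_min) break
      sel <- c(sel, u)
      queue <- c(queue, u)
    }
  }
  if (length(sel) < instance$k_min) return(fallback)
  if (!check_feasible(instance, sel, root, tags = FALSE)$feasible) {
    return(fallback)
  }
  if (any(vapply(cuts, function(cc) setequal(cc, sel), logical(1)))) {
    return(fallback)
  }
  mean(instance$score[sel])
}

#' Find the optimal average-score subgraph
#'
#' Maximizes (or minimizes) the average node score over all feasible
#' root-connected subgraphs by the Dinkelbach iterative scheme: starting
#' from the average score of a greedy feasible subgraph, the parametric
#' problem `max s^T x - lambda * e^T x` is solved exactly and `lambda` is
#' updated to the incumbent's average score until the parametric optimum is
#' within `gap_tolerance` of zero. For maximization the `lambda` sequence
#' is non-decreasing. Reverse mode is solved as forward mode on the
#' edge-reversed network with receptors and terminals swapped; the node set
#' is reported in the original orientation.
#'
#' @param instance A [deregnet_instance()].
#' @param settings A [solver_settings()].
#' @param cuts List of node sets excluded as whole solutions (used by
#'   [solve_suboptimal()]).
#' @return A `deregnet_solution` with fields `nodes`, `root`, `objective`
#'   (average score), `total_score`, `rank`, `converged` and the visited
#'   `lambdas`.
#' @export
deregnet_solve <- function(instance, settings = solver_settings(),
                           cuts = list()) {
  stopifnot(inherits(instance, "deregnet_instance"))
  eff <- effective_instance(instance)
  lambda <- greedy_lambda0(eff, cuts)
  lambdas <- lambda
  res <- NULL
  objective <- NA_real_
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(settings$max_iterations)) {
    iters <- it
    res <- parametric_core(eff, lambda, settings, cuts)
    objective <- mean(eff$score[res$nodes])
    if (abs(res$value) <= settings$gap_tolerance) {
      converged <- TRUE
      break
    }
    lambda <- objective
    lambdas <- c(lambdas, lambda)
  }
  new_solution(nodes = res$nodes, root = res$root, objective = objective,
               total_score = sum(eff$score[res$nodes]), rank = 0L,
               converged = converged, lambdas = lambdas, instance = instance,
               iterations = iters, gap = res$value)
}

#' @rdname deregnet_solve
#' @param a A [deregnet_instance()] (S3 method for [base::solve()]).
#' @param b A [solver_settings()].
#' @param ... Unused.
#' @export
solve.deregnet_instance <- function(a, b = solver_settings(), ...) {
  deregnet_solve(a, b)
}

#' Fixed-size comparator: best total-score subgraph of exactly k nodes
#'
#' Maximizes the linear objective `s^T x` over root-connected subgraphs of
#' exactly `k` nodes (the fixed-subgraph-size model this method is
#' benchmarked against). Receptor and terminal sets are optional; with both
#' empty any node may be the root and the sink condition is dropped.
#'
#' @param g An igraph object.
#' @param scores Score table (tibble with `node`, `score`) or named vector.
#' @param k Exact subgraph size.
#' @param receptors,terminals Optional node sets as in
#'   [deregnet_instance()].
#' @param settings A [solver_settings()].
#' @return A `deregnet_solution`; `total_score` holds `s^T x`.
#' @export
solve_fixed_size <- function(g, scores, k, receptors = character(),
                             terminals = character(),
                             settings = solver_settings()) {
  stopifnot(k >= 1, k <= igraph::vcount(g))
  inst <- deregnet_instance(g, scores, receptors = receptors,
                            terminals = terminals, k_min = k, k_max = k,
                            sense = "maximize")
  res <- core_call(inst, inst$score, settings, cuts = list())
  if (!res$feasible) {
    if (res$hit_limit) timeout_error(NULL) else infeasible_error()
  }
  if (res$hit_limit) {
    timeout_error(incumbent = list(nodes = res$nodes, root = res$root_name,
                                   value = res$value))
  }
  verify_emitted(inst, res$nodes, res$root_name)
  new_solution(nodes = res$nodes, root = res$root_name,
               objective = res$value / k, total_score = res$value, rank = 0L,
               converged = TRUE, lambdas = numeric(0), instance = inst,
               iterations = 1L)
}

#' Union of fixed-size solutions over a size range
#'
#' Runs [solve_fixed_size()] for every `k` in `[k_min, k_max]` and returns
#' the union of the returned node sets -- the strategy used to run the
#' fixed-size model when only size bounds are known. Sizes whose model is
#' infeasible or hits the solver limits are skipped with a message.
#'
#' @inheritParams solve_fixed_size
#' @param k_min,k_max Size range.
#' @return Sorted character vector: the union node set.
#' @export
solve_union_over_sizes <- function(g, scores, k_min, k_max,
                                   receptors = character(),
                                   terminals = character(),
                                   settings = solver_settings()) {
  stopifnot(k_min <= k_max)
  sets <- list()
  for (k in seq(k_min, k_max)) {
    sol <- tryCatch(
      solve_fixed_size(g, scores, k, receptors, terminals, settings),
      deregnet_infeasible = function(e) {
        message(sprintf("size k = %d infeasible; skipped", k))
        NULL
      },
      deregnet_timeout = function(e) {
        message(sprintf("size k = %d hit solver limits; skipped", k))
        NULL
      })
    if (!is.null(sol)) sets[[length(sets) + 1L]] <- sol$nodes
  }
  if (length(sets) == 0L) {
    infeasible_error("all sizes in the range were infeasible")
  }
  sort(unique(unlist(sets)))
}

#' Enumerate the optimal and next-best suboptimal subgraphs
#'
#' Repeatedly solves the instance, after each solution appending a no-good
#' cut that forbids returning that exact node set again -- the weakest
#' exclusion guaranteeing a different node set, so supersets of earlier
#' solutions remain admissible. Objectives are non-increasing across ranks
#' for maximization. Stops early when the cut-augmented instance becomes
#' infeasible.
#'
#' @inheritParams deregnet_solve
#' @param n Number of suboptimal solutions requested beyond the optimum.
#' @return List of `deregnet_solution` objects with ranks `0..n` (possibly
#'   fewer when the feasible pool is exhausted).
#' @export
solve_suboptimal <- function(instance, n = 4L, settings = solver_settings()) {
  stopifnot(n >= 0)
  sols <- list()
  cuts <- list()
  for (rank in 0:n) {
    sol <- tryCatch(deregnet_solve(instance, settings, cuts = cuts),
                    deregnet_infeasible = function(e) NULL)
    if (is.null(sol)) {
      if (rank == 0L) infeasible_error()
      break
    }
    sol$rank <- rank
    sols[[length(sols) + 1L]] <- sol
    cuts[[length(cuts) + 1L]] <- sol$nodes
  }
  sols
}

#' Summarize solutions as an annotated union subgraph
#'
#' Builds the subgraph of the network induced by the union of all solution
#' node sets; each node carries its occurrence count across solutions in
#' the `frequency` vertex attribute, and roots are flagged in `is_root`.
#'
#' @param solutions Non-empty list of `deregnet_solution` objects (or a
#'   single solution).
#' @param g The underlying igraph network.
#' @return An igraph object with `frequency`, `score` and `is_root` vertex
#'   attributes.
#' @export
union_summary <- function(solutions, g) {
  if (inherits(solutions, "deregnet_solution")) solutions <- list(solutions)
  stopifnot(length(solutions) > 0L)
  sets <- lapply(solutions, `[[`, "nodes")
  all_sel <- sort(unique(unlist(sets)))
  counts <- table(factor(unlist(sets), levels = all_sel))
  sub <- igraph::induced_subgraph(g, all_sel)
  igraph::V(sub)$frequency <- as.integer(counts[igraph::V(sub)$name])
  roots <- unique(vapply(solutions, `[[`, "", "root"))
  igraph::V(sub)$is_root <- igraph::V(sub)$name %in% roots
  sc <- solutions[[1L]]$score
  full <- stats::setNames(rep(NA_real_, length(all_sel)), all_sel)
  full[names(sc)] <- sc
  igraph::V(sub)$score <- unname(full[igraph::V(sub)$name])
  sub
}

#' Exhaustive enumeration oracle for small instances
#'
#' Enumerates every candidate (node set, root) pair within the size bounds,
#' filters by [check_feasible()] and returns the best average score. Ties
#' are broken toward the lexicographically smallest sorted node set. Kept
#' deliberately independent of the branch-and-bound path so it can serve
#' as a correctness oracle.
#'
#' @param instance A [deregnet_instance()].
#' @param cap Refuse networks larger than this many nodes.
#' @return A `deregnet_solution` (rank 0, `converged = TRUE`).
#' @export
brute_force_optimal <- function(instance, cap = 15L) {
  stopifnot(inherits(instance, "deregnet_instance"))
  eff <- effective_instance(instance)
  nodes <- sort(names(eff$score))
  if (length(nodes) > cap) {
    stop("brute_force_optimal: network exceeds the enumeration cap",
         call. = FALSE)
  }
  maximize <- eff$sense == "maximize"
  best_obj <- NULL
  best_set <- NULL
  best_root <- NULL
  best_key <- NULL
  for (size in seq(eff$k_min, eff$k_max)) {
    sets <- utils::combn(nodes, size, simplify = FALSE)
    for (S in sets) {
      if (any(eff$exclude %in% S)) next
      if (!all(eff$include %in% S)) next
      roots <- if (length(eff$receptors) > 0L) {
        intersect(S, eff$receptors)
      } else S
      root_ok <- NULL
      for (r in roots) {
        if (check_feasible(eff, S, r, tags = FALSE)$feasible) {
          root_ok <- r
          break
        }
      }
      if (is.null(root_ok)) next
      obj <- mean(eff$score[S])
      key <- paste(S, collapse = ",")
      better <- is.null(best_obj) ||
        (if (maximize) obj > best_obj + 1e-12 else obj < best_obj - 1e-12) ||
        (abs(obj - best_obj) <= 1e-12 && key < best_key)
      if (better) {
        best_obj <- obj
        best_set <- S
        best_root <- root_ok
        best_key <- key
      }
    }
  }
  if (is.null(best_set)) infeasible_error()
  new_solution(nodes = best_set, root = best_root, objective = best_obj,
               total_score = sum(eff$score[best_set]), rank = 0L,
               converged = TRUE, lambdas = numeric(0), instance = instance,
               iterations = NA_integer_)
}

#' Serialize a solution to GraphML plus a JSON sidecar
#'
#' Writes the induced subgraph as GraphML (node attributes `score`,
#' `is_root`, `frequency`) and a JSON file with the node set, root,
#' objective, total score, rank, convergence flag and size bounds.
#'
#' @param solution A `deregnet_solution`.
#' @param g The underlying igraph network.
#' @param path_prefix Output path prefix; `.graphml` and `.json` are
#'   appended.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_solution <- function(solution, g, path_prefix) {
  sub <- union_summary(list(solution), g)
  gml <- paste0(path_prefix, ".graphml")
  jsn <- paste0(path_prefix, ".json")
  igraph::write_graph(sub, gml, format = "graphml")
  jsonlite::write_json(
    list(nodes = solution$nodes, root = solution$root,
         objective = solution$objective, total_score = solution$total_score,
         rank = solution$rank, converged = solution$converged,
         k_min = solution$k_min, k_max = solution$k_max,
         sense = solution$sense),
    jsn, auto_unbox = TRUE, digits = NA)
  invisible(c(gml, jsn))
}
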