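#' Define a subgraph-inference instance
#'
#' Bundles a directed network, a node score, the optional receptor (allowed
#' roots), terminal (allowed sinks), include and exclude node sets, the
#' subgraph size bounds and the optimization sense/mode into a validated
#' instance object. The optimal subgraph of an instance is the feasible
#' root-connected subgraph maximizing (or minimizing) the average node
#' score.
#'
#' @param g An igraph object (see [deregnet_network()]).
#' @param scores A tibble with columns `node` and `score`, or a named
#'   numeric vector. Network nodes without a score get 0.
#' @param receptors,terminals,include,exclude Character vectors of node ids
#'   (all optional). When `receptors` is non-empty the root must be a
#'   receptor; when `terminals` is non-empty every subgraph node without a
#'   selected out-neighbor must be a terminal.
#' @param k_min,k_max Inclusive bounds on the subgraph size (defaults 10 and
#'   50, a reasonable range of expected pathway sizes).
#' @param sense `"maximize"` or `"minimize"` the average score.
#' @param absolute Use the element-wise absolute value of the score.
#' @param mode `"forward"`, or `"reverse"` to solve on the edge-reversed
#'   network with receptor/terminal roles swapped (subgraphs that converge
#'   into a single terminal node).
#' @return An object of class `deregnet_instance`.
#' @export
deregnet_instance <- function(g, scores, receptors = character(),
                              terminals = character(), include = character(),
                              exclude = character(), k_min = 10, k_max = 50,
                              sense = c("maximize", "minimize"),
                              absolute = FALSE,
                              mode = c("forward", "reverse")) {
  sense <- match.arg(sense)
  mode <- match.arg(mode)
  stopifnot(igraph::is_igraph(g), igraph::is_directed(g))
  nodes <- igraph::V(g)$name
  if (!(k_min >= 1 && k_min <= k_max && k_min <= length(nodes))) {
    stop("size bounds must satisfy 1 <= k_min <= k_max and k_min <= |V|",
         call. = FALSE)
  }
  k_max <- min(k_max, length(nodes))  # a bound beyond |V| is never binding
  receptors <- unique(check_subset(g, receptors, "receptors"))
  terminals <- unique(check_subset(g, terminals, "terminals"))
  include <- unique(check_subset(g, include, "include"))
  exclude <- unique(check_subset(g, exclude, "exclude"))
  if (length(intersect(include, exclude)) > 0L) {
    stop("include and exclude sets must be disjoint", call. = FALSE)
  }
  if (length(include) > k_max) {
    stop("include set larger than k_max", call. = FALSE)
  }
  adj <- adjacency_lists(g)
  structure(
    list(graph = g, score = score_vector(g, scores), receptors = receptors,
         terminals = terminals, include = include, exclude = exclude,
         k_min = k_min, k_max = k_max, sense = sense, absolute = absolute,
         mode = mode, out_adj = adj$out, in_adj = adj$`in`),
    class = "deregnet_instance"
  )
}

adjacency_lists <- function(g) {
  nodes <- igraph::V(g)$name
  out <- lapply(igraph::adjacent_vertices(g, nodes, mode = "out"),
                function(v) sort(names(v)))
  names(out) <- nodes
  inn <- lapply(igraph::adjacent_vertices(g, nodes, mode = "in"),
                function(v) sort(names(v)))
  names(inn) <- nodes
  list(out = out, `in` = inn)
}

#' @export
print.deregnet_instance <- function(x, ...) {
  cat(sprintf(
    "<deregnet_instance> %d nodes, %d edges | k in [%d, %d] | %s%s%s\n",
    igraph::vcount(x$graph), igraph::gsize(x$graph), x$k_min, x$k_max,
    x$sense, if (x$absolute) " |s|" else "",
    if (x$mode == "reverse") " (reverse mode)" else ""))
  cat(sprintf("  receptors: %d, terminals: %d, include: %d, exclude: %d\n",
              length(x$receptors), length(x$terminals), length(x$include),
              length(x$exclude)))
  invisible(x)
}

# Resolve absolute scoring and reverse mode into a plain forward instance.
# Node identities are unchanged, so solutions map back one-to-one.
effective_instance <- function(instance) {
  if (instance$absolute) {
    instance$score <- abs(instance$score)
    instance$absolute <- FALSE
  }
  if (instance$mode == "reverse") {
    tmp <- instance$out_adj
    instance$out_adj <- instance$in_adj
    instance$in_adj <- tmp
    tmpset <- instance$receptors
    instance$receptors <- instance$terminals
    instance$terminals <- tmpset
    instance$graph <- igraph::reverse_edges(instance$graph)
    instance$mode <- "forward"
  }
  instance
}

#' Solver settings
#'
#' @param gap_tolerance Convergence tolerance for the iterative
#'   ratio-update (Dinkelbach) scheme: the loop stops once the parametric
#'   optimum is within this value of zero.
#' @param max_iterations Maximum number of ratio updates.
#' @param time_limit Time limit in seconds per parametric solve.
#' @param node_limit Branch-and-bound search-node limit per parametric
#'   solve.
#' @param random_seed Retained for provenance records; the bundled
#'   branch-and-bound backend is deterministic.
#' @param suboptimal_strategy Strategy for enumerating next-best solutions;
#'   only `"nogood-cut"` (exclude each previously returned node set) is
#'   implemented.
#' @param backend Solver backend label; only the bundled exact
#'   branch-and-bound (`"bnb"`) is available.
#' @return A list of class `deregnet_settings`.
#' @export
solver_settings <- function(gap_tolerance = 1e-6, max_iterations = 50,
                            time_limit = 600, node_limit = 5e7,
                            random_seed = 1L,
                            suboptimal_strategy = "nogood-cut",
                            backend = "bnb") {
  stopifnot(gap_tolerance > 0, max_iterations >= 1)
  structure(list(gap_tolerance = gap_tolerance,
                 max_iterations = as.integer(max_iterations),
                 time_limit = time_limit, node_limit = node_limit,
                 random_seed = as.integer(random_seed),
                 suboptimal_strategy = match.arg(suboptimal_strategy,
                                                 "nogood-cut"),
                 backend = backend),
            class = "deregnet_settings")
}

infeasible_error <- function(msg = "no feasible subgraph under the given constraints") {
  stop(errorCondition(msg, class = c("deregnet_infeasible", "deregnet_error")))
}

timeout_error <- function(incumbent = NULL) {
  stop(errorCondition("solver time or search-node limit reached",
                      incumbent = incumbent,
                      class = c("deregnet_timeout", "deregnet_error")))
}
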