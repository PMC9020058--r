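#' Check a candidate subgraph against the instance's constraint system
#'
#' Verifies a (node set, root) pair against every constraint of the model:
#' root selected and unique, size bounds, root-is-receptor, terminal
#' condition (selected non-terminal nodes keep a selected out-neighbor),
#' include/exclude membership, the in-neighbor condition for non-root
#' nodes, the strongly-connected-component condition, and directed
#' reachability of every selected node from the root inside the selection
#' (the latter is equivalent to the two connectivity constraint families
#' combined).
#'
#' @param instance A [deregnet_instance()].
#' @param nodes Character vector: the candidate node set.
#' @param root Single node id; must be a network node.
#' @param tags When `TRUE` (default), failed checks are reported with
#'   constraint tags (`"1b"`, `"1d"`--`"1j"`, `"reachability"`); when
#'   `FALSE` only overall feasibility is computed (faster).
#' @return A list with `feasible` (logical) and `violated` (character
#'   vector of constraint tags, empty when feasible or `tags = FALSE`).
#' @export
check_feasible <- function(instance, nodes, root, tags = TRUE) {
  stopifnot(inherits(instance, "deregnet_instance"))
  instance <- effective_instance(instance)
  all_nodes <- names(instance$score)
  if (length(root) != 1L || !root %in% all_nodes) {
    stop("root must be a single network node", call. = FALSE)
  }
  nodes <- unique(as.character(nodes))
  if (!all(nodes %in% all_nodes)) {
    stop("candidate node set contains ids not in the network", call. = FALSE)
  }
  out_adj <- instance$out_adj
  in_adj <- instance$in_adj
  violated <- character()
  root_in <- root %in% nodes
  if (!root_in) violated <- c(violated, "1b")
  if (length(nodes) < instance$k_min || length(nodes) > instance$k_max) {
    violated <- c(violated, "1d")
  }
  if (length(instance$receptors) > 0L && !root %in% instance$receptors) {
    violated <- c(violated, "1g")
  }
  if (length(instance$terminals) > 0L) {
    nonterm <- setdiff(nodes, instance$terminals)
    ok_1h <- all(vapply(nonterm, function(v) any(out_adj[[v]] %in% nodes),
                        logical(1)))
    if (!ok_1h) violated <- c(violated, "1h")
  }
  if (!all(instance$include %in% nodes)) violated <- c(violated, "1i")
  if (any(instance$exclude %in% nodes)) violated <- c(violated, "1j")

  reachable <- root_in &&
    length(reach_within(out_adj, nodes, root)) == length(nodes)
  if (!tags) {
    feasible <- length(violated) == 0L && reachable
    return(list(feasible = feasible, violated = character()))
  }
  if (root_in && !reachable) {
    violated <- c(violated, "reachability")
    others <- setdiff(nodes, root)
    ok_1e <- all(vapply(others, function(v) any(in_adj[[v]] %in% nodes),
                        logical(1)))
    if (!ok_1e) violated <- c(violated, "1e")
    if (length(scc_violations(out_adj, in_adj, nodes, root)) > 0L) {
      violated <- c(violated, "1f")
    }
  }
  ord <- c("1b", "1d", "1e", "1f", "1g", "1h", "1i", "1j", "reachability")
  violated <- intersect(ord, violated)
  list(feasible = length(violated) == 0L, violated = violated)
}

# Nodes of `nodes` reachable from root by directed paths inside `nodes`.
reach_within <- function(out_adj, nodes, root) {
  seen <- stats::setNames(logical(length(nodes)), nodes)
  if (!root %in% nodes) return(character())
  seen[root] <- TRUE
  queue <- root
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]
    head <- head + 1L
    nb <- out_adj[[v]]
    nb <- nb[nb %in% nodes]
    fresh <- nb[!seen[nb]]
    if (length(fresh) > 0L) {
      seen[fresh] <- TRUE
      queue <- c(queue, fresh)
    }
  }
  names(seen)[seen]
}

# Kosaraju-style SCC partition of the subgraph induced by `nodes`,
# on plain adjacency lists. Returns a list of sorted character vectors
# ordered by smallest member.
scc_within <- function(out_adj, in_adj, nodes) {
  if (length(nodes) == 0L) return(list())
  nodes <- sort(nodes)
  inset <- stats::setNames(rep(TRUE, length(nodes)), nodes)
  visited <- stats::setNames(logical(length(nodes)), nodes)
  order_stack <- character(0)
  for (s in nodes) {
    if (visited[s]) next
    # iterative DFS with explicit stack, recording finish order
    stack <- list(list(v = s, i = 0L))
    visited[s] <- TRUE
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]
      nb <- out_adj[[top$v]]
      nb <- nb[nb %in% nodes]
      advanced <- FALSE
      while (top$i < length(nb)) {
        top$i <- top$i + 1L
        u <- nb[top$i]
        if (!visited[u]) {
          visited[u] <- TRUE
          stack[[length(stack)]] <- top
          stack[[length(stack) + 1L]] <- list(v = u, i = 0L)
          advanced <- TRUE
          break
        }
      }
      if (!advanced) {
        order_stack <- c(order_stack, top$v)
        stack[[length(stack)]] <- NULL
      }
    }
  }
  assigned <- stats::setNames(logical(length(nodes)), nodes)
  comps <- list()
  for (s in rev(order_stack)) {
    if (assigned[s]) next
    comp <- character(0)
    queue <- s
    assigned[s] <- TRUE
    head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]
      head <- head + 1L
      comp <- c(comp, v)
      nb <- in_adj[[v]]
      nb <- nb[nb %in% nodes]
      fresh <- nb[!assigned[nb]]
      if (length(fresh) > 0L) {
        assigned[fresh] <- TRUE
        queue <- c(queue, fresh)
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, `[`, "", 1L))]
}

# SCCs of the subgraph induced by `nodes` that violate the connectivity
# constraint family: size > 1, root not a member, and no incoming edge
# from a selected node outside the component.
scc_violations <- function(out_adj, in_adj, nodes, root) {
  comps <- scc_within(out_adj, in_adj, nodes)
  Filter(function(S) {
    if (length(S) <= 1L || root %in% S) return(FALSE)
    outside <- setdiff(nodes, S)
    !any(vapply(S, function(v) any(in_adj[[v]] %in% outside), logical(1)))
  }, comps)
}

#' Find strongly connected components violating root-connectivity
#'
#' Returns every strongly connected component of the subgraph induced by
#' `nodes` that has more than one member, does not contain the root, and
#' has no incoming edge from another selected node -- exactly the
#' components whose connectivity constraint is violated by the candidate
#' solution. During solving, emitted solutions are verified to yield an
#' empty violation list.
#'
#' @inheritParams check_feasible
#' @return List of character vectors (possibly empty), ordered by smallest
#'   member.
#' @export
separate_scc_violations <- function(instance, nodes, root) {
  stopifnot(inherits(instance, "deregnet_instance"))
  nodes <- unique(as.character(nodes))
  if (!all(nodes %in% names(instance$score))) {
    stop("candidate node set contains ids not in the network", call. = FALSE)
  }
  scc_violations(instance$out_adj, instance$in_adj, nodes, root)
}
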