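# Shared fixture builders. Everything is generated in code; no files.

# Three-node feed-forward motif A -> B -> C with shortcut A -> C.
triangle_graph <- function() {
  deregnet_network(data.frame(source = c("A", "A", "B"),
                              target = c("B", "C", "C")))
}

triangle_instance <- function(scores = c(A = 1, B = 0, C = 1), k_min = 2,
                              k_max = 3, ...) {
  deregnet_instance(triangle_graph(), scores, receptors = "A",
                    terminals = "C", k_min = k_min, k_max = k_max, ...)
}

# Random simple digraph on n nodes; may contain isolated nodes.
random_digraph <- function(n, density = 2) {
  ids <- sprintf("v%02d", seq_len(n))
  m <- max(1L, rpois(1, density * n))
  from <- sample(ids, m, replace = TRUE)
  to <- sample(ids, m, replace = TRUE)
  keep <- from != to
  if (!any(keep)) {
    from <- ids[1L]
    to <- ids[2L]
    keep <- TRUE
  }
  deregnet_network(data.frame(source = from[keep], target = to[keep]),
                   nodes = ids)
}

# Random small instance in the oracle-checkable regime: |V| <= 12,
# k in [2, 5], receptor/terminal sets of size 0-3, uniform scores.
random_small_instance <- function(senses = c("maximize", "minimize"),
                                  absolutes = c(TRUE, FALSE),
                                  modes = "forward") {
  n <- sample(5:12, 1L)
  g <- random_digraph(n)
  ids <- igraph::V(g)$name
  s <- stats::setNames(round(stats::runif(n, -2, 2), 2), ids)
  deregnet_instance(
    g, s,
    receptors = sample(ids, sample(0:3, 1L)),
    terminals = sample(ids, sample(0:3, 1L)),
    k_min = 2L, k_max = 5L,
    sense = sample(senses, 1L),
    absolute = sample(absolutes, 1L),
    mode = sample(modes, 1L)
  )
}

# All feasible node sets of a small instance, by exhaustive enumeration
# over subsets and roots (independent of the solver path).
enumerate_feasible_sets <- function(inst) {
  ids <- sort(names(inst$score))
  out <- list()
  for (size in inst$k_min:inst$k_max) {
    for (S in utils::combn(ids, size, simplify = FALSE)) {
      roots <- if (length(inst$receptors) > 0L) {
        intersect(S, inst$receptors)
      } else S
      for (r in roots) {
        if (check_feasible(inst, S, r, tags = FALSE)$feasible) {
          out[[length(out) + 1L]] <- S
          break
        }
      }
    }
  }
  out
}

# Survival fixture: two events in group A at t = 1, 2 and two in group B
# at t = 3, 4 (used for the worked log-rank example).
logrank_fixture <- function() {
  list(
    a = data.frame(patient_id = c("a1", "a2"), time = c(1, 2),
                   event = c(1, 1)),
    b = data.frame(patient_id = c("b1", "b2"), time = c(3, 4),
                   event = c(1, 1))
  )
}
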