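# Evaluate the RNG-dependent `code` under a temporary seed, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

resample <- function(x, n = 1L) x[sample.int(length(x), n)]

#' Generate a synthetic directed scale-free network
#'
#' Preferential-attachment growth with randomized edge orientation: each
#' new node attaches to `round(out_degree_param)` existing nodes chosen
#' with probability proportional to degree + 1, and each new edge points
#' toward or away from the new node with equal probability. The result is
#' a simple directed graph (no self-loops, no duplicate edges) that stands
#' in for a curated regulatory network in simulation studies, and is fully
#' deterministic given `seed`.
#'
#' @param n_nodes Number of nodes (at least 2).
#' @param out_degree_param Average number of edges brought in per node
#'   (positive; default 2).
#' @param seed Integer seed.
#' @return An igraph object.
#' @export
generate_network <- function(n_nodes, out_degree_param = 2, seed = 1L) {
  if (n_nodes < 2 || out_degree_param <= 0) {
    stop("need n_nodes >= 2 and out_degree_param > 0", call. = FALSE)
  }
  m <- max(1L, as.integer(round(out_degree_param)))
  with_seed(seed, {
    deg <- rep(0L, n_nodes)
    from <- integer(0)
    to <- integer(0)
    from <- 1L
    to <- 2L
    deg[1:2] <- 1L
    if (n_nodes > 2L) {
      for (i in 3:n_nodes) {
        k <- min(m, i - 1L)
        targets <- sample.int(i - 1L, k, prob = deg[seq_len(i - 1L)] + 1)
        for (t in targets) {
          if (stats::runif(1) < 0.5) {
            from <- c(from, i)
            to <- c(to, t)
          } else {
            from <- c(from, t)
            to <- c(to, i)
          }
        }
        deg[targets] <- deg[targets] + 1L
        deg[i] <- deg[i] + k
      }
    }
    fmt <- paste0("n%0", nchar(as.character(n_nodes)), "d")
    ids <- sprintf(fmt, seq_len(n_nodes))
    deregnet_network(data.frame(source = ids[from], target = ids[to]))
  })
}

#' Plant a random root-connected subgraph
#'
#' Draws a target size uniformly from `[size_min, size_max]`, starts from a
#' uniformly random root and repeatedly adds a uniformly random unused
#' out-neighbor of a uniformly random current member until the target size
#' is reached. When growth dead-ends (no member has an unused
#' out-neighbor) the process restarts from a fresh root, up to
#' `max_retries` times. Uses the current RNG state; seed the caller.
#'
#' @param g An igraph object.
#' @param size_min,size_max Inclusive bounds on the planted size.
#' @param max_retries Restart budget before giving up (default 1000).
#' @return List with `nodes` (sorted character vector) and `root`.
#' @export
simulate_true_subgraph <- function(g, size_min, size_max,
                                   max_retries = 1000L) {
  nodes <- igraph::V(g)$name
  stopifnot(size_min >= 1, size_min <= size_max, size_max <= length(nodes))
  out_adj <- adjacency_lists(g)$out
  k <- resample(seq(size_min, size_max))
  for (try in seq_len(max_retries)) {
    root <- resample(nodes)
    vs <- root
    repeat {
      if (length(vs) >= k) {
        return(list(nodes = sort(vs), root = root))
      }
      growable <- vs[vapply(vs, function(v) {
        length(setdiff(out_adj[[v]], vs)) > 0L
      }, logical(1))]
      if (length(growable) == 0L) break
      v <- resample(growable)
      u <- resample(setdiff(out_adj[[v]], vs))
      vs <- c(vs, u)
    }
  }
  stop("graph too sparse: could not grow a planted subgraph of size ", k,
       " in ", max_retries, " attempts", call. = FALSE)
}

#' Simulate binary deregulation scores around a planted subgraph
#'
#' Independent Bernoulli draws: nodes inside `V_sub` score 1 with
#' probability `p_prime`, nodes outside with probability `p`. Uses the
#' current RNG state.
#'
#' @param g An igraph object.
#' @param V_sub Character vector: the planted subgraph.
#' @param p,p_prime Outside and inside deregulation probabilities.
#' @return Named numeric 0/1 vector over all nodes.
#' @export
simulate_scores <- function(g, V_sub, p, p_prime) {
  nodes <- igraph::V(g)$name
  stopifnot(all(V_sub %in% nodes))
  inside <- nodes %in% V_sub
  s <- numeric(length(nodes))
  s[inside] <- stats::rbinom(sum(inside), 1L, p_prime)
  s[!inside] <- stats::rbinom(sum(!inside), 1L, p)
  stats::setNames(s, nodes)
}

#' Node-recovery metrics for a predicted versus planted subgraph
#'
#' Treats predicted-subgraph membership as a binary classification of the
#' `n_total` network nodes and reports the confusion counts along with
#' sensitivity (TPR), precision, F1, Jaccard index, Matthews correlation
#' coefficient and size efficiency (predicted size over true size; 1 is
#' ideal). Zero denominators yield 0 for precision and MCC.
#'
#' @param V_pred Predicted node set.
#' @param V_true Planted (true) node set; must be non-empty.
#' @param n_total Number of nodes in the network.
#' @return One-row tibble.
#' @export
evaluate_subgraph <- function(V_pred, V_true, n_total) {
  V_pred <- unique(as.character(V_pred))
  V_true <- unique(as.character(V_true))
  if (length(V_true) == 0L) stop("true subgraph must be non-empty", call. = FALSE)
  tp <- length(intersect(V_pred, V_true))
  fp <- length(setdiff(V_pred, V_true))
  fn <- length(setdiff(V_true, V_pred))
  tn <- n_total - tp - fp - fn
  prec <- if (length(V_pred) == 0L) 0 else tp / length(V_pred)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    tpr = tp / length(V_true),
    precision = prec,
    f1 = 2 * tp / (2 * tp + fp + fn),
    jaccard = tp / length(union(V_pred, V_true)),
    mcc = mcc,
    size_efficiency = length(V_pred) / length(V_true)
  )
}

#' Hypergeometric gene-set enrichment p-value
#'
#' Upper-tail hypergeometric probability of observing at least the
#' realized overlap between `gene_set` and `deregulated` when drawing
#' `|gene_set|` genes from the universe without replacement.
#'
#' @param gene_set Character vector (e.g. an inferred subgraph's nodes).
#' @param deregulated Character vector of deregulated genes.
#' @param universe Character vector: the gene universe.
#' @return The enrichment p-value.
#' @export
hypergeom_enrichment <- function(gene_set, deregulated, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  gene_set <- unique(as.character(gene_set))
  deregulated <- unique(as.character(deregulated))
  stopifnot(all(gene_set %in% universe), all(deregulated %in% universe))
  overlap <- length(intersect(gene_set, deregulated))
  stats::phyper(overlap - 1, m = length(deregulated),
                n = length(universe) - length(deregulated),
                k = length(gene_set), lower.tail = FALSE)
}

#' Simulation benchmark configuration
#'
#' Defaults are the scaled study conditions used throughout the package's
#' simulation experiments: near-deterministic in-subgraph deregulation
#' (`p_prime = 0.99`) over a low background rate (`p = 0.01`), planted
#' sizes 8--12, and search bounds 6--15 around them.
#'
#' @param p,p_prime Outside / inside deregulation probabilities,
#'   `0 < p < p_prime <= 1`.
#' @param true_size_min,true_size_max Planted-subgraph size bounds.
#' @param k_min,k_max Size bounds handed to the solvers.
#' @param n_instances Number of simulated instances.
#' @param time_limit Seconds per parametric solve.
#' @param seed Master seed; per-instance streams are derived from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(p = 0.01, p_prime = 0.99, true_size_min = 8L,
                              true_size_max = 12L, k_min = 6L, k_max = 15L,
                              n_instances = 20L, time_limit = 600,
                              seed = 1L) {
  if (!(p > 0 && p < p_prime && p_prime <= 1)) {
    stop("require 0 < p < p_prime <= 1", call. = FALSE)
  }
  stopifnot(true_size_min <= true_size_max, k_min <= k_max, n_instances >= 0)
  structure(list(p = p, p_prime = p_prime,
                 true_size_min = as.integer(true_size_min),
                 true_size_max = as.integer(true_size_max),
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 n_instances = as.integer(n_instances),
                 time_limit = time_limit, seed = as.integer(seed)),
            class = "simulation_config")
}

benchmark_row <- function(instance_id, seed, algorithm, pred, truth,
                          n_total, dereg, universe, runtime, converged,
                          error = NA_character_) {
  if (is.null(pred)) {
    metrics <- tibble::tibble(tp = NA_integer_, fp = NA_integer_,
                              fn = NA_integer_, tn = NA_integer_,
                              tpr = NA_real_, precision = NA_real_,
                              f1 = NA_real_, jaccard = NA_real_,
                              mcc = NA_real_, size_efficiency = NA_real_)
    enr <- NA_real_
    n_pred <- NA_integer_
  } else {
    metrics <- evaluate_subgraph(pred, truth, n_total)
    enr <- hypergeom_enrichment(pred, dereg, universe)
    n_pred <- length(pred)
  }
  dplyr::bind_cols(
    tibble::tibble(instance = instance_id, seed = seed,
                   algorithm = algorithm, n_true = length(truth),
                   n_pred = n_pred),
    metrics,
    tibble::tibble(enrichment_p = enr, runtime = runtime,
                   converged = converged, error = error)
  )
}

#' Run the planted-subgraph recovery benchmark
#'
#' For each simulated instance (planted root-connected subgraph plus
#' Bernoulli scores) the benchmark runs (a) the average-score model with
#' size bounds `[k_min, k_max]` and (b) the fixed-size comparator as a
#' union over every size in the same range (free root, no receptor or
#' terminal sets), then records recovery metrics, runtimes and the
#' hypergeometric enrichment p-value of each emitted subgraph against the
#' simulated scores. Per-instance RNG streams are derived from
#' `config$seed` and the instance index, so results are fully reproducible
#' and individual instances can be regenerated independently. Solver
#' failures are logged per instance (NA metrics) without aborting the run.
#'
#' @param g An igraph object (e.g. from [generate_network()]).
#' @param config A [simulation_config()].
#' @param settings A [solver_settings()]; defaults to the config's time
#'   limit.
#' @return A tibble (class `deregnet_benchmark`) with one row per instance
#'   and algorithm.
#' @export
run_benchmark <- function(g, config,
                          settings = solver_settings(time_limit = config$time_limit)) {
  stopifnot(inherits(config, "simulation_config"))
  universe <- igraph::V(g)$name
  rows <- list()
  for (i in seq_len(config$n_instances)) {
    iseed <- as.integer((config$seed + 7919 * i) %% 2147483647)
    sim <- with_seed(iseed, {
      truth <- simulate_true_subgraph(g, config$true_size_min,
                                      config$true_size_max)
      scores <- simulate_scores(g, truth$nodes, config$p, config$p_prime)
      list(truth = truth, scores = scores)
    })
    dereg <- names(sim$scores)[sim$scores == 1]

    t0 <- proc.time()[["elapsed"]]
    drn <- tryCatch(
      deregnet_solve(
        deregnet_instance(g, sim$scores, k_min = config$k_min,
                          k_max = config$k_max, sense = "maximize"),
        settings),
      deregnet_error = function(e) {
        message(sprintf("instance %d: solver failed (%s)", i,
                        conditionMessage(e)))
        e
      })
    t_drn <- proc.time()[["elapsed"]] - t0
    rows[[length(rows) + 1L]] <- if (inherits(drn, "deregnet_solution")) {
      benchmark_row(i, iseed, "deregnet", drn$nodes, sim$truth$nodes,
                    length(universe), dereg, universe, t_drn, drn$converged)
    } else {
      benchmark_row(i, iseed, "deregnet", NULL, sim$truth$nodes,
                    length(universe), dereg, universe, t_drn, NA,
                    conditionMessage(drn))
    }

    t0 <- proc.time()[["elapsed"]]
    cmp <- tryCatch(
      solve_union_over_sizes(g, sim$scores, config$k_min, config$k_max,
                             settings = settings),
      deregnet_error = function(e) {
        message(sprintf("instance %d: comparator failed (%s)", i,
                        conditionMessage(e)))
        e
      })
    t_cmp <- proc.time()[["elapsed"]] - t0
    rows[[length(rows) + 1L]] <- if (is.character(cmp)) {
      benchmark_row(i, iseed, "fixed_size_union", cmp, sim$truth$nodes,
                    length(universe), dereg, universe, t_cmp, TRUE)
    } else {
      benchmark_row(i, iseed, "fixed_size_union", NULL, sim$truth$nodes,
                    length(universe), dereg, universe, t_cmp, NA,
                    conditionMessage(cmp))
    }
  }
  out <- if (length(rows) == 0L) {
    benchmark_row(1L, 1L, "deregnet", character(), "x", 1L, character(),
                  "x", 0, NA)[0L, ]
  } else {
    dplyr::bind_rows(rows)
  }
  class(out) <- c("deregnet_benchmark", class(out))
  out
}

#' Box plots of benchmark metrics by algorithm
#'
#' @param object A tibble from [run_benchmark()].
#' @param metrics Which metric columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deregnet_benchmark <- function(object,
                                        metrics = c("mcc", "f1", "jaccard",
                                                    "precision", "tpr",
                                                    "size_efficiency"),
                                        ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "algorithm",
                  dplyr::all_of(metrics)),
    cols = dplyr::all_of(metrics), names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$algorithm, y = .data$value,
                                     fill = .data$algorithm)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw()
}
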