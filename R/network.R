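#' Build a directed interaction network
#'
#' Constructs the directed, simple (no self-loops, no duplicate edges) graph
#' over opaque string node identifiers that all other functions in the
#' package operate on. Input is either an edge table or an existing igraph
#' object; the result is always a normalized igraph object: self-loops are
#' dropped with a warning, parallel edges are collapsed (the first
#' interaction label wins) and vertices are ordered by sorted name so that
#' downstream iteration, solver input and output are reproducible.
#'
#' @param edges A data frame with columns `source` and `target` (and
#'   optionally `interaction`), or an igraph object.
#' @param nodes Optional character vector of additional (possibly isolated)
#'   node ids.
#' @return An igraph object (directed, simple, named vertices).
#' @examples
#' g <- deregnet_network(data.frame(source = "A", interaction = "activation",
#'                                  target = "B"))
#' igraph::gsize(g)
#' @export
deregnet_network <- function(edges, nodes = NULL) {
  if (igraph::is_igraph(edges)) {
    g <- edges
    if (!igraph::is_directed(g)) {
      stop("network must be a directed graph", call. = FALSE)
    }
    if (is.null(igraph::V(g)$name)) {
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    }
  } else {
    edges <- as.data.frame(edges)
    if (!all(c("source", "target") %in% names(edges))) {
      stop("edge table needs `source` and `target` columns", call. = FALSE)
    }
    ids <- unique(c(as.character(edges$source), as.character(edges$target),
                    as.character(nodes)))
    if (length(ids) == 0L) stop("network has an empty node set", call. = FALSE)
    g <- igraph::make_empty_graph(directed = TRUE) +
      igraph::vertices(sort(ids))
    if (nrow(edges) > 0L) {
      g <- igraph::add_edges(
        g, rbind(as.character(edges$source), as.character(edges$target))
      )
      if ("interaction" %in% names(edges)) {
        igraph::E(g)$interaction <- as.character(edges$interaction)
      }
    }
  }
  normalize_network(g)
}

# Drop self-loops (warn), collapse duplicate edges, sort vertices by name.
normalize_network <- function(g) {
  if (igraph::vcount(g) == 0L) stop("network has an empty node set", call. = FALSE)
  n_loops <- sum(igraph::which_loop(g))
  if (n_loops > 0L) {
    warning(sprintf("dropped %d self-loop(s)", n_loops), call. = FALSE)
  }
  comb <- if (is.null(igraph::edge_attr(g)$interaction)) "ignore" else {
    list(interaction = "first", "ignore")
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = comb)
  igraph::permute(g, order(order(igraph::V(g)$name)))
}

#' Read a network from SIF-like TSV or GraphML
#'
#' The SIF-TSV dialect is tab-separated `source <TAB> interaction <TAB>
#' target`, one edge per line, no header; the interaction token is kept as
#' the `interaction` edge attribute. GraphML is parsed by igraph. Both
#' formats go through the same normalization as [deregnet_network()].
#'
#' @param path Path to the network file.
#' @param format `"sif"` or `"graphml"`.
#' @return An igraph object.
#' @export
read_network <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)
  if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("network has an empty node set", call. = FALSE)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) != 3L)
    if (length(bad) > 0L) {
      stop(sprintf("SIF parse failure at line %d: expected 3 tab-separated fields",
                   bad[1L]), call. = FALSE)
    }
    tab <- do.call(rbind, parts)
    deregnet_network(data.frame(source = tab[, 1L], interaction = tab[, 2L],
                                target = tab[, 3L], stringsAsFactors = FALSE))
  } else {
    validate_graphml(path)
    g <- tryCatch(
      igraph::read_graph(path, format = "graphml"),
      error = function(e) stop("GraphML parse failure: ", conditionMessage(e),
                               call. = FALSE)
    )
    if (is.null(igraph::V(g)$name)) {
      if (!is.null(igraph::V(g)$id)) {
        igraph::V(g)$name <- igraph::V(g)$id
      } else {
        igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
      }
    }
    if (!igraph::is_directed(g)) {
      g <- igraph::as_directed(g, mode = "arbitrary")
    }
    normalize_network(g)
  }
}

#' Write a network (or induced subgraph) to GraphML
#'
#' @param g An igraph object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# igraph silently materializes edge endpoints that were never declared as
# <node> elements, so endpoint declarations are checked up front.
validate_graphml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("GraphML parse failure: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  node_ids <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//*[local-name() = 'node']"), "id")
  edges <- xml2::xml_find_all(doc, ".//*[local-name() = 'edge']")
  endpoints <- c(xml2::xml_attr(edges, "source"),
                 xml2::xml_attr(edges, "target"))
  undeclared <- setdiff(endpoints, node_ids)
  if (length(undeclared) > 0L) {
    stop("GraphML parse failure: edge references undeclared node '",
         undeclared[1L], "'", call. = FALSE)
  }
  invisible(TRUE)
}

check_subset <- function(g, nodes, what = "node set") {
  nodes <- as.character(nodes)
  missing <- setdiff(nodes, igraph::V(g)$name)
  if (length(missing) > 0L) {
    stop(sprintf("%s contains ids not in the network: %s", what,
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  }
  nodes
}

#' Out- and in-neighborhoods of a node set
#'
#' `out_neighbors()` returns the outgoing boundary of `S`: all nodes outside
#' `S` that receive an edge from some member of `S`. `in_neighbors()` is the
#' mirror image (incoming boundary). Members of `S` are never returned.
#'
#' @param g An igraph object.
#' @param S Character vector of node ids, `S` must be a subset of the nodes.
#' @return Sorted character vector of node ids.
#' @export
out_neighbors <- function(g, S) {
  S <- check_subset(g, S, "S")
  if (length(S) == 0L) return(character())
  nb <- unique(unlist(lapply(igraph::adjacent_vertices(g, S, mode = "out"),
                             names)))
  sort(setdiff(as.character(nb), S))
}

#' @rdname out_neighbors
#' @export
in_neighbors <- function(g, S) {
  S <- check_subset(g, S, "S")
  if (length(S) == 0L) return(character())
  nb <- unique(unlist(lapply(igraph::adjacent_vertices(g, S, mode = "in"),
                             names)))
  sort(setdiff(as.character(nb), S))
}

#' Strongly connected components of an induced subgraph
#'
#' Partitions `restrict` into the strongly connected components of the
#' subgraph induced by `restrict`. The components are returned sorted by
#' their smallest member id, and each component is itself sorted, so the
#' output is deterministic.
#'
#' @param g An igraph object.
#' @param restrict Character vector of node ids (defaults to all nodes).
#' @return List of character vectors partitioning `restrict`.
#' @export
scc_partition <- function(g, restrict = igraph::V(g)$name) {
  restrict <- check_subset(g, restrict, "restrict")
  if (length(restrict) == 0L) return(list())
  sub <- igraph::induced_subgraph(g, restrict)
  comp <- igraph::components(sub, mode = "strong")
  parts <- unname(split(igraph::V(sub)$name, comp$membership))
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[`, "", 1L))]
}

#' Reverse the orientation of every edge
#'
#' Used for reverse-mode subgraph inference: solving on the reversed network
#' with receptor and terminal roles swapped yields subgraphs in which a
#' single terminal node is reachable from every other subgraph node.
#' Edge attributes are carried over.
#'
#' @param g An igraph object.
#' @return The reversed igraph object.
#' @export
reverse_network <- function(g) {
  normalize_network(igraph::reverse_edges(g))
}

#' Read a one-id-per-line node list
#'
#' @param path Path to a plain-text file, one node id per line.
#' @return Character vector (possibly empty); blank lines are skipped.
#' @export
read_node_list <- function(path) {
  if (!file.exists(path)) stop("node list file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Read and write node-score tables
#'
#' Score tables are two-column TSV files (`node`, `score`), no header
#' required on read (a `node<TAB>score` header line is tolerated).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `node` (character) and `score` (double).
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("score file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("node", "score"))
  if (identical(tolower(tab$node[1L]), "node")) tab <- tab[-1L, , drop = FALSE]
  tibble::tibble(node = as.character(tab$node), score = as.numeric(tab$score))
}

#' @rdname read_score_table
#' @param scores A tibble/data frame with columns `node` and `score`.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(scores[, c("node", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Align a score table with a network
#'
#' Returns a full named score vector over the network's nodes. Network nodes
#' missing from the table get a neutral score of 0; table ids absent from
#' the network are ignored (a message reports how many).
#'
#' @param g An igraph object.
#' @param scores A tibble/data frame with columns `node` and `score`, or a
#'   named numeric vector.
#' @return Named numeric vector ordered like `igraph::V(g)$name`.
#' @export
score_vector <- function(g, scores) {
  if (is.numeric(scores) && !is.null(names(scores))) {
    scores <- tibble::tibble(node = names(scores), score = unname(scores))
  }
  stopifnot(all(c("node", "score") %in% names(scores)))
  if (anyDuplicated(scores$node)) {
    stop("duplicate node ids in score table", call. = FALSE)
  }
  nodes <- igraph::V(g)$name
  extra <- setdiff(scores$node, nodes)
  if (length(extra) > 0L) {
    message(sprintf("ignoring %d score id(s) not present in the network",
                    length(extra)))
  }
  s <- stats::setNames(rep(0, length(nodes)), nodes)
  keep <- scores$node %in% nodes
  s[scores$node[keep]] <- scores$score[keep]
  s
}
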