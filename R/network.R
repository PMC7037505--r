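#' Small-world network specification
#'
#' Parameters of the Watts-Strogatz construction used to represent the
#' kin/friendship network along which evacuation decisions diffuse.
#'
#' @param n_nodes Number of evacuees (nodes), at least 3.
#' @param k_ring Even number of nearest neighbours per node in the base ring
#'   lattice (`k_ring/2` on each side), `2 <= k_ring < n_nodes`.
#' @param p_rewire Probability of rewiring each lattice edge, in \[0, 1\].
#' @param seed Integer RNG seed for the construction.
#'
#' @return An object of class `network_spec`.
#' @examples
#' network_spec(n_nodes = 200, k_ring = 4, p_rewire = 0.1, seed = 1)
#' @export
network_spec <- function(n_nodes = 200, k_ring = 4, p_rewire = 0.1, seed = 1) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 3 ||
      n_nodes != round(n_nodes))
    stop("network_spec: 'n_nodes' must be an integer >= 3", call. = FALSE)
  if (!is.numeric(k_ring) || length(k_ring) != 1L || k_ring != round(k_ring) ||
      k_ring %% 2 != 0 || k_ring < 2 || k_ring >= n_nodes)
    stop("network_spec: 'k_ring' must be an even integer with ",
         "2 <= k_ring < n_nodes", call. = FALSE)
  if (!is.numeric(p_rewire) || length(p_rewire) != 1L || !is.finite(p_rewire) ||
      p_rewire < 0 || p_rewire > 1)
    stop("network_spec: 'p_rewire' must be in [0, 1]", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))
    stop("network_spec: 'seed' must be an integer", call. = FALSE)
  structure(list(n_nodes = as.integer(n_nodes), k_ring = as.integer(k_ring),
                 p_rewire = p_rewire, seed = as.integer(seed)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("Small-world spec: N=%d K=%d p_rewire=%.3g seed=%d\n",
              x$n_nodes, x$k_ring, x$p_rewire, x$seed))
  invisible(x)
}

#' Generate a connected Watts-Strogatz small-world graph
#'
#' Builds a ring lattice in which every node is joined to `k_ring/2`
#' neighbours on each side, then rewires each original edge with probability
#' `p_rewire` to a uniformly chosen target, forbidding self-loops and
#' parallel edges so that the edge count `n_nodes * k_ring / 2` is conserved.
#' Because decision diffusion on a disconnected graph silently biases the
#' evacuation response rate, a disconnected draw is discarded and the
#' construction retried with an incremented seed (up to `max_attempts`).
#'
#' @param spec A [network_spec()].
#' @param max_attempts Maximum regeneration attempts for connectivity.
#' @return An undirected simple [igraph::igraph] graph with graph attributes
#'   recording the spec and the seed actually used.
#' @examples
#' g <- generate_small_world(network_spec(50, 4, 0.1, seed = 7))
#' igraph::ecount(g)  # 100 edges
#' @export
generate_small_world <- function(spec, max_attempts = 100) {
  stopifnot(inherits(spec, "network_spec"))
  seed <- spec$seed
  for (attempt in seq_len(max_attempts)) {
    g <- withr::with_seed(seed, igraph::sample_smallworld(
      dim = 1, size = spec$n_nodes, nei = spec$k_ring %/% 2,
      p = spec$p_rewire, loops = FALSE, multiple = FALSE))
    if (igraph::is_connected(g)) {
      g <- igraph::set_graph_attr(g, "n_nodes", spec$n_nodes)
      g <- igraph::set_graph_attr(g, "k_ring", spec$k_ring)
      g <- igraph::set_graph_attr(g, "p_rewire", spec$p_rewire)
      g <- igraph::set_graph_attr(g, "seed", spec$seed)
      g <- igraph::set_graph_attr(g, "seed_used", seed)
      return(g)
    }
    message("generate_small_world: draw with seed ", seed,
            " disconnected; retrying with seed ", seed + 1L)
    seed <- seed + 1L
  }
  stop("generate_small_world: no connected graph in ", max_attempts,
       " attempts", call. = FALSE)
}

#' Neighbour-selection distribution of a node
#'
#' Probability with which node `i` selects each neighbour as its information
#' exchange partner: adjacency weight normalised over the neighbourhood,
#' \eqn{p_{ij} = A_{ij} / \sum_{k \in \Omega_i} A_{ik}}. For the unweighted
#' graphs the package ships this is uniform over neighbours; an edge
#' attribute `weight` is honoured if present.
#'
#' @param graph An [igraph::igraph] graph.
#' @param i Node id (1-based igraph vertex id).
#' @return Named numeric vector of probabilities over the neighbours of `i`,
#'   summing to 1.
#' @export
neighbor_choice_distribution <- function(graph, i) {
  stopifnot(igraph::is_igraph(graph))
  if (i < 1 || i > igraph::vcount(graph))
    stop("neighbor_choice_distribution: node ", i, " not in graph",
         call. = FALSE)
  edges <- igraph::incident(graph, i)
  if (length(edges) == 0)
    stop("neighbor_choice_distribution: node ", i, " is isolated",
         call. = FALSE)
  nbrs <- as.integer(igraph::neighbors(graph, i))
  w <- if ("weight" %in% igraph::edge_attr_names(graph)) {
    igraph::edge_attr(graph, "weight", edges)
  } else {
    rep(1, length(nbrs))
  }
  p <- w / sum(w)
  names(p) <- nbrs
  p
}

#' Summary statistics of an interaction graph
#'
#' Degree histogram, mean local clustering coefficient, and mean shortest
#' path length. For a disconnected graph the path length is computed on the
#' largest component and flagged.
#'
#' @param graph An [igraph::igraph] graph.
#' @return A list with `n_nodes`, `n_edges`, `degree_histogram` (table),
#'   `mean_degree`, `mean_clustering`, `mean_path_length`, `connected`.
#' @export
graph_statistics <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  connected <- igraph::is_connected(graph)
  gp <- graph
  if (!connected) {
    comp <- igraph::components(graph)
    gp <- igraph::induced_subgraph(graph,
                                   which(comp$membership == which.max(comp$csize)))
  }
  cl <- igraph::transitivity(graph, type = "localundirected", isolates = "zero")
  list(n_nodes = igraph::vcount(graph),
       n_edges = igraph::ecount(graph),
       degree_histogram = table(igraph::degree(graph)),
       mean_degree = mean(igraph::degree(graph)),
       mean_clustering = mean(cl),
       mean_path_length = igraph::mean_distance(gp, directed = FALSE),
       connected = connected)
}

#' Read / write a graph as a whitespace-delimited edge list
#'
#' Plain-text interchange of the interaction graph: one edge per line, two
#' 0-based node indices. `write_edgelist()` also accepts `format =
#' "graphml"`.
#'
#' @param graph An [igraph::igraph] graph.
#' @param path File path.
#' @param format `"edgelist"` (default) or `"graphml"`.
#' @return `read_edgelist()` returns an undirected igraph graph;
#'   `write_edgelist()` returns `path` invisibly.
#' @export
write_edgelist <- function(graph, path, format = c("edgelist", "graphml")) {
  stopifnot(igraph::is_igraph(graph))
  format <- match.arg(format)
  igraph::write_graph(graph, path, format = format)
  invisible(path)
}

#' @rdname write_edgelist
#' @param n_nodes Optional node count for `read_edgelist()`, for graphs with
#'   trailing isolated nodes not mentioned in the edge list.
#' @export
read_edgelist <- function(path, n_nodes = NULL) {
  el <- as.matrix(utils::read.table(path, header = FALSE,
                                    col.names = c("from", "to")))
  n <- if (is.null(n_nodes)) max(el) + 1L else n_nodes
  igraph::graph_from_edgelist(el + 1L, directed = FALSE) |>
    igraph::add_vertices(max(0L, n - max(el) - 1L))
}
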