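## Network construction, coercion and I/O.
##
## Networks are plain igraph objects constrained to be simple, undirected,
## unweighted and connected; assert_network() enforces those invariants and
## every generator/reader in the package returns a graph that passes it.

#' Validate a network for use with the dynamics models
#'
#' Checks that a graph is a simple (no self-loops, no multi-edges),
#' undirected, unweighted, connected graph with at least two nodes, the only
#' kind of network the dynamics models are defined on.
#'
#' @param net An igraph object.
#' @return The graph, invisibly, if all invariants hold; otherwise an error.
#' @export
assert_network <- function(net) {
  if (!igraph::is_igraph(net)) stop("`net` must be an igraph object")
  if (igraph::vcount(net) < 2L) stop("network must have at least 2 nodes")
  if (igraph::is_directed(net)) stop("network must be undirected")
  if (igraph::any_loop(net)) stop("network must not contain self-loops")
  if (igraph::any_multiple(net)) stop("network must not contain duplicate edges")
  if ("weight" %in% igraph::edge_attr_names(net))
    stop("network must be unweighted (edge attribute 'weight' present)")
  if (!igraph::is_connected(net)) stop("network must be connected")
  invisible(net)
}

#' Adjacency matrix of a network
#'
#' @param net A network passing [assert_network()].
#' @return A dense numeric 0/1 matrix.
#' @export
adjacency <- function(net) {
  as.matrix(igraph::as_adjacency_matrix(net, type = "both", sparse = TRUE))
}

## 0-based endpoint vectors used by the compiled integrator.
edge_ends0 <- function(net) {
  e <- igraph::as_edgelist(net, names = FALSE)
  list(from = as.integer(e[, 1] - 1L), to = as.integer(e[, 2] - 1L))
}

#' Periodic square lattice
#'
#' Builds a `side` x `side` square lattice with periodic boundary conditions
#' (a torus), so every node has degree exactly 4 and there are `2 * side^2`
#' edges.
#'
#' @param side Integer number of nodes per lattice dimension; must be at
#'   least 3, because for `side < 3` the wrap-around edge duplicates an
#'   existing edge (the graph would not be simple).
#' @return An igraph network with `side^2` nodes.
#' @examples
#' net <- make_periodic_lattice(10)
#' igraph::vcount(net)  # 100
#' @export
make_periodic_lattice <- function(side) {
  side <- as.integer(side)
  if (length(side) != 1L || is.na(side) || side < 3L)
    stop("`side` must be >= 3: on a torus with side < 3 the wrap-around ",
         "edge duplicates an existing edge, producing a non-simple graph")
  idx <- function(r, c) ((r - 1L) %% side) * side + ((c - 1L) %% side) + 1L
  rc <- expand.grid(r = seq_len(side), c = seq_len(side))
  right <- cbind(idx(rc$r, rc$c), idx(rc$r, rc$c + 1L))
  down  <- cbind(idx(rc$r, rc$c), idx(rc$r + 1L, rc$c))
  net <- igraph::graph_from_edgelist(rbind(right, down), directed = FALSE)
  assert_network(net)
}

#' Generate a synthetic network from a standard random-graph family
#'
#' Wraps the igraph generators behind a single seeded interface. If the raw
#' draw is disconnected, only the largest connected component is returned, so
#' the result may have fewer than `n` nodes.
#'
#' @param family One of `"barabasi_albert"`, `"erdos_renyi"`,
#'   `"watts_strogatz"`, `"configuration"`.
#' @param n Number of nodes requested (before largest-component coercion).
#' @param seed Integer seed; equal arguments give an identical edge set.
#' @param m Attachment count for `barabasi_albert` (default 2, giving mean
#'   degree about 4, comparable to the periodic lattice).
#' @param p Edge probability (`erdos_renyi`) or rewiring probability
#'   (`watts_strogatz`).
#' @param nei Neighbourhood radius for `watts_strogatz` (default 2).
#' @param degrees Degree sequence for `configuration`.
#' @return An igraph network passing [assert_network()].
#' @export
make_model_network <- function(family = c("barabasi_albert", "erdos_renyi",
                                          "watts_strogatz", "configuration"),
                               n, seed, m = 2, p = NULL, nei = 2,
                               degrees = NULL) {
  family <- match.arg(family)
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be at least 2")
  set.seed(as.integer(seed))
  g <- switch(family,
    barabasi_albert = {
      if (m < 1) stop("attachment count `m` must be >= 1")
      igraph::sample_pa(n, m = m, directed = FALSE)
    },
    erdos_renyi = {
      if (is.null(p)) stop("`p` is required for erdos_renyi")
      igraph::sample_gnp(n, p = p)
    },
    watts_strogatz = {
      if (is.null(p)) stop("rewiring probability `p` is required for watts_strogatz")
      igraph::sample_smallworld(1, n, nei = nei, p = p)
    },
    configuration = {
      if (is.null(degrees)) stop("`degrees` is required for configuration")
      if (length(degrees) != n) stop("`degrees` must have length `n`")
      igraph::sample_degseq(degrees, method = "vl")
    })
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g <- largest_component(g)
  if (igraph::vcount(g) < 2L)
    stop("parameters cannot yield a connected network of >= 2 nodes ",
         "after largest-component coercion")
  assert_network(g)
}

largest_component <- function(g) {
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  igraph::induced_subgraph(g, keep)
}

#' Read a network from a plain-text edge list
#'
#' One edge per line, two (or more) whitespace-separated node labels; extra
#' columns such as weights are ignored, as are blank lines and lines starting
#' with `#`. The graph is coerced to an undirected, unweighted simple graph:
#' reciprocal and duplicate lines collapse to one edge, self-loops are
#' dropped (with a warning), and only the largest connected component is
#' retained.
#'
#' @param path Path to the edge-list file.
#' @return An igraph network whose vertex attribute `name` holds the original
#'   labels of the retained nodes; the attribute `label_map` on the graph is
#'   a data frame mapping label to 0-based internal index.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  from <- character(0); to <- character(0)
  for (i in which(keep)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 2L)
      stop("unreadable edge on line ", i, ": need at least two node labels")
    from <- c(from, tok[1]); to <- c(to, tok[2])
  }
  if (length(from) == 0L) stop("empty edge list: no edges found in ", path)
  loops <- from == to
  if (any(loops)) {
    warning(sum(loops), " self-loop line(s) dropped")
    from <- from[!loops]; to <- to[!loops]
  }
  if (length(from) == 0L)
    stop("no edges remain after dropping self-loops in ", path)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g <- largest_component(g)
  if (igraph::vcount(g) < 2L) stop("no usable edges after coercion in ", path)
  labels <- igraph::V(g)$name
  g <- igraph::set_graph_attr(g, "label_map",
    data.frame(label = labels, index = seq_along(labels) - 1L,
               stringsAsFactors = FALSE))
  assert_network(g)
}

#' Write a network as a canonical edge list
#'
#' Emits one edge per line with the two labels sorted within the line and
#' lines sorted lexicographically, so equal graphs produce identical files.
#'
#' @param net A network; vertex names are used as labels when present,
#'   otherwise 1-based indices.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  assert_network(net)
  e <- igraph::as_edgelist(net, names = !is.null(igraph::V(net)$name))
  e <- t(apply(e, 1, function(r) sort(as.character(r))))
  lines <- sort(paste(e[, 1], e[, 2]))
  writeLines(lines, path)
  invisible(path)
}
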