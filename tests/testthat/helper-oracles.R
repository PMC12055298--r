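# Independent brute-force oracles and small fixture builders. The oracles
# re-derive each statistic from its definition with naive loops, so they
# share no code with the package implementations.

brute_morans_i <- function(x, A) {
  n <- length(x)
  xb <- mean(x)
  W <- 0; num <- 0
  for (i in 1:n) for (j in 1:n) {
    W <- W + A[i, j]
    num <- num + A[i, j] * (x[i] - xb) * (x[j] - xb)
  }
  (n / W) * num / sum((x - xb)^2)
}

brute_moment <- function(x, k) {
  xb <- mean(x)
  s <- 0
  for (xi in x) s <- s + (xi - xb)^k
  s / length(x)
}

brute_sd <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))
brute_cv <- function(x) brute_sd(x) / mean(x)
brute_skew <- function(x) brute_moment(x, 3) / brute_moment(x, 2)^1.5
brute_kurt <- function(x) brute_moment(x, 4) / brute_moment(x, 2)^2

# Kendall tau-b by explicit pair counting with tie correction.
brute_kendall_taub <- function(x, y) {
  n <- length(x)
  nc <- 0; nd <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[j] - x[i]); b <- sign(y[j] - y[i])
    if (a == 0 && b == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (a == 0) tx <- tx + 1
    else if (b == 0) ty <- ty + 1
    else if (a == b) nc <- nc + 1
    else nd <- nd + 1
  }
  n0 <- n * (n - 1) / 2
  (nc - nd) / sqrt((n0 - tx) * (n0 - ty))
}

# A random connected simple graph on n nodes: a random spanning tree plus a
# few random extra edges.
random_connected_graph <- function(n, seed) {
  set.seed(seed)
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1, 1), 1L))
  extra <- max(0L, stats::rbinom(1, n, 0.4))
  if (extra > 0) {
    more <- t(replicate(extra, sort(sample.int(n, 2))))
    edges <- rbind(edges, more)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

# Minimal sweep_result object with prescribed labels, for home-range tests.
fake_sweep <- function(labels, direction = "ascending",
                       param_range = c(0, 1), states = NULL) {
  L <- nrow(labels)
  grid <- seq(param_range[1], param_range[2], length.out = L)
  if (direction == "descending") grid <- rev(grid)
  structure(list(
    param_grid = grid,
    states = if (is.null(states))
      matrix(rnorm(length(labels)), nrow = L) else states,
    labels = labels,
    spec = model_spec("double_well", "u"),
    cfg = sweep_config(param_range, direction, L = max(L, 10)),
    n_nodes = ncol(labels)), class = "sweep_result")
}

two_node_graph <- function() igraph::make_graph(c(1, 2), directed = FALSE)
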