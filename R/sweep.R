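## Control-parameter sweeps: grid protocol, home-range extraction and
## automatic simulation-range search.

#' Configuration of a control-parameter sweep
#'
#' @param param_range Numeric `c(low, high)` with `low < high`: the
#'   simulation range of the control parameter.
#' @param direction `"ascending"` (traverse low to high, start in the lower
#'   state) or `"descending"` (traverse high to low, start in the upper
#'   state).
#' @param L Number of evenly spaced grid points (default 100).
#' @param dt Euler-Maruyama step size (default 0.01).
#' @param t_equil Equilibration horizon per grid point in time units
#'   (default 50); exactly one snapshot is taken at `t = t_equil`.
#' @param seed Integer master seed for the sweep; each grid point gets its
#'   own deterministic child stream, so changing `L` does not shuffle noise
#'   across unrelated points.
#' @return An object of class `"sweep_config"`.
#' @export
sweep_config <- function(param_range, direction = c("ascending", "descending"),
                         L = 100, dt = 0.01, t_equil = 50, seed = 1) {
  direction <- match.arg(direction)
  if (length(param_range) != 2L || !all(is.finite(param_range)) ||
      param_range[1] >= param_range[2])
    stop("`param_range` must be c(low, high) with low < high")
  if (L < 10) stop("`L` must be at least 10")
  if (dt <= 0) stop("`dt` must be positive")
  if (t_equil < dt) stop("`t_equil` must be at least `dt`")
  structure(list(param_range = as.numeric(param_range), direction = direction,
                 L = as.integer(L), dt = dt, t_equil = t_equil,
                 seed = as.integer(seed)),
            class = "sweep_config")
}

## Deterministic child seed for grid point `i` (1-based) of a sweep seeded
## with `seed`. Pure integer arithmetic in doubles (exact below 2^53),
## reduced mod the largest 32-bit prime.
child_seed <- function(seed, i) {
  v <- (as.double(seed) %% 2147483647) * 48271 + 104729 * as.double(i)
  as.integer(v %% 2147483647)
}

#' Run a control-parameter sweep
#'
#' For each of the `L` grid values in traversal order, reinitializes the
#' system at [initial_state()] (no continuation between grid points),
#' integrates for `t_equil` time units and records the single equilibrated
#' snapshot `x*` (one sample per node). Noise is independent across grid
#' points and reproducible given the sweep seed.
#'
#' @param spec A [model_spec()].
#' @param net Network the dynamics run on.
#' @param cfg A [sweep_config()].
#' @return An object of class `"sweep_result"`: a list with `param_grid`
#'   (length `L`, in traversal order), `states` (`L x N` matrix of
#'   equilibrated states), `labels` (`L x N` character matrix over
#'   `"lower"`/`"upper"`), and `spec`, `cfg`, `n_nodes`.
#' @export
run_sweep <- function(spec, net, cfg) {
  stopifnot(inherits(spec, "model_spec"), inherits(cfg, "sweep_config"))
  assert_network(net)
  n <- igraph::vcount(net)
  x0 <- initial_state(spec, cfg$direction, n)
  grid <- seq(cfg$param_range[1], cfg$param_range[2], length.out = cfg$L)
  if (cfg$direction == "descending") grid <- rev(grid)
  states <- matrix(NA_real_, nrow = cfg$L, ncol = n)
  for (i in seq_len(cfg$L)) {
    du <- resolve_Du(spec, grid[i])
    set.seed(child_seed(cfg$seed, i))
    states[i, ] <- integrate_em(spec, net, D = du$D, u = du$u, x0 = x0,
                                dt = cfg$dt, t_end = cfg$t_equil)
  }
  labels <- matrix(classify_node_state(spec, as.numeric(t(states))),
                   nrow = cfg$L, byrow = TRUE)
  structure(list(param_grid = grid, states = states, labels = labels,
                 spec = spec, cfg = cfg, n_nodes = n),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ", x$spec$model_id, " / ", x$spec$control, " / ",
      x$cfg$direction, "\n", sep = "")
  cat("  ", x$cfg$L, " grid points in [",
      format(min(x$param_grid)), ", ", format(max(x$param_grid)), "], ",
      x$n_nodes, " nodes\n", sep = "")
  tipped <- tryCatch(find_home_range(x), error = function(e) NA_integer_)
  if (!is.na(tipped))
    cat("  home range: first ", tipped, " grid points\n", sep = "")
  invisible(x)
}

#' Extract the home range of a sweep
#'
#' The home range is the leading portion of the sweep (in traversal order)
#' over which every node is still in its initial state class; it ends
#' immediately before the first tipping point, the first grid row at which
#' at least one node has left that class.
#'
#' @param result A [run_sweep()] result.
#' @return Integer `k`, the number of leading grid points in the home range
#'   (`1 <= k < L`).
#' @export
find_home_range <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  init_class <- if (result$cfg$direction == "ascending") "lower" else "upper"
  tipped_row <- apply(result$labels != init_class, 1, any)
  if (tipped_row[1])
    stop("tipping precedes simulation range: the first grid point already ",
         "contains a node outside the ", init_class, " state")
  if (!any(tipped_row))
    stop("no tipping point in simulation range: no node ever leaves the ",
         init_class, " state")
  which(tipped_row)[1] - 1L
}

#' Search for a usable simulation range
#'
#' Replaces by-hand trial and error: starting from a bracket, repeatedly
#' runs a coarse pilot sweep (`L_pilot` points) and adjusts the range until
#' (i) all nodes are untipped at the first grid point, (ii) at least one
#' node has tipped by the last, and (iii) the pilot home range covers at
#' least `min_home_frac` of the grid. If no tipping occurs the range is
#' extended away from the start; if tipping occurs too early the far end is
#' pulled in so the tipping point sits about 70% of the way through.
#' Deterministic given `seed`.
#'
#' @param spec A [model_spec()].
#' @param net Network.
#' @param direction `"ascending"` or `"descending"`.
#' @param bracket Starting `c(low, high)` range.
#' @param L_pilot Pilot grid size (default 20).
#' @param dt,t_equil Integration settings for the pilots.
#' @param seed Integer seed for the pilot sweeps.
#' @param max_iter Expansion/zoom iteration cap (default 12).
#' @param min_home_frac Minimum home-range fraction of the pilot grid
#'   (default 0.4).
#' @return Numeric `c(low, high)` satisfying the pilot post-condition. A
#'   bracket already satisfying it is returned unchanged.
#' @export
search_simulation_range <- function(spec, net, direction, bracket,
                                    L_pilot = 20, dt = 0.01, t_equil = 50,
                                    seed = 1, max_iter = 12,
                                    min_home_frac = 0.4) {
  stopifnot(inherits(spec, "model_spec"))
  direction <- match.arg(direction, c("ascending", "descending"))
  lo <- bracket[1]; hi <- bracket[2]
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("`bracket` must be c(low, high) with low < high")
  floor_lo <- if (spec$control == "D") 0 else -Inf
  for (iter in seq_len(max_iter)) {
    cfg <- sweep_config(c(lo, hi), direction, L = L_pilot, dt = dt,
                        t_equil = t_equil, seed = child_seed(seed, iter))
    res <- run_sweep(spec, net, cfg)
    init_class <- if (direction == "ascending") "lower" else "upper"
    tipped_row <- apply(res$labels != init_class, 1, any)
    width <- hi - lo
    if (tipped_row[1]) {
      ## start already tipped: move the start away from the tipping region
      if (direction == "ascending") lo <- max(floor_lo, lo - width)
      else hi <- hi + width
      next
    }
    if (!any(tipped_row)) {
      ## no tipping: extend the far end
      if (direction == "ascending") hi <- hi + width
      else lo <- max(floor_lo, lo - 2 * width)
      if (direction == "descending" && lo == 0 && bracket_stuck(res, floor_lo))
        stop("expansion limit: range cannot be extended below 0 and no ",
             "tipping point was found")
      next
    }
    k <- which(tipped_row)[1] - 1L
    if (k / L_pilot >= min_home_frac) return(c(lo, hi))
    ## tipping too close to the start: pull the far end in so the tipping
    ## value sits ~70% of the way through the range
    tip_val <- res$param_grid[k + 1L]
    if (direction == "ascending") hi <- lo + (tip_val - lo) / 0.7
    else lo <- max(floor_lo, hi - (hi - tip_val) / 0.7)
  }
  stop("expansion limit reached (", max_iter, " pilot iterations) without ",
       "bracketing a tipping point with a sufficient home range")
}

bracket_stuck <- function(res, floor_lo) {
  is.finite(floor_lo) && abs(min(res$param_grid) - floor_lo) < 1e-12
}

#' Write / read a sweep result as tidy CSV plus a JSON sidecar
#'
#' The CSV holds one row per (grid point, node) with columns `param_index`,
#' `param_value`, `node`, `x_star`, `label` at full float precision; the
#' sidecar `<path>.json` captures the model spec and sweep configuration so
#' the pair round-trips losslessly.
#'
#' @param result A [run_sweep()] result.
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly (for the writer); a `"sweep_result"` (reader).
#' @export
write_sweep_csv <- function(result, path) {
  stopifnot(inherits(result, "sweep_result"))
  L <- result$cfg$L; n <- result$n_nodes
  df <- data.frame(param_index = rep(seq_len(L), each = n),
                   param_value = rep(result$param_grid, each = n),
                   node = rep(seq_len(n), times = L),
                   x_star = as.numeric(t(result$states)),
                   label = as.character(t(result$labels)))
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(spec = unclass(result$spec), cfg = unclass(result$cfg),
               n_nodes = result$n_nodes)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- model_spec(meta$spec$model_id, meta$spec$control,
                     params = as.list(meta$spec$params),
                     sigma = meta$spec$sigma,
                     fixed_value = meta$spec$fixed_value)
  cfg <- sweep_config(meta$cfg$param_range, meta$cfg$direction,
                      L = meta$cfg$L, dt = meta$cfg$dt,
                      t_equil = meta$cfg$t_equil, seed = meta$cfg$seed)
  L <- cfg$L; n <- meta$n_nodes
  ord <- order(df$param_index, df$node)
  df <- df[ord, ]
  structure(list(
    param_grid = df$param_value[seq(1, nrow(df), by = n)],
    states = matrix(df$x_star, nrow = L, ncol = n, byrow = TRUE),
    labels = matrix(df$label, nrow = L, ncol = n, byrow = TRUE),
    spec = spec, cfg = cfg, n_nodes = n), class = "sweep_result")
}
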