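## End-to-end orchestration: the condition matrix, per-sweep evaluation,
## multi-network experiments and the square-lattice reproduction experiment.

#' The ten retained simulation conditions
#'
#' A simulation condition is a (dynamics model, control parameter,
#' direction) triple. Of the 16 nominal combinations, six are dropped as
#' unrealistic: the mutualistic and gene-regulatory models are only
#' simulated descending (the scientific question is collapse of the extant
#' or active state), and the SIS model has no stress parameter `u`. The
#' ten retained conditions are returned in a fixed, deterministic order.
#'
#' @return A data frame with columns `model_id`, `control`, `direction`.
#' @export
enumerate_conditions <- function() {
  data.frame(
    model_id = c("double_well", "double_well", "double_well", "double_well",
                 "mutualistic", "mutualistic", "sis", "sis", "gene", "gene"),
    control = c("u", "u", "D", "D", "u", "D", "D", "D", "u", "D"),
    direction = c("ascending", "descending", "ascending", "descending",
                  "descending", "descending", "ascending", "descending",
                  "descending", "descending"),
    stringsAsFactors = FALSE)
}

#' Shipped simulation ranges for the lattice conditions
#'
#' Default simulation ranges for the ten conditions on the 10 x 10 periodic
#' lattice, discovered once with [search_simulation_range()] under a fixed
#' seed and frozen here. `fixed_value` is the value of the non-control
#' parameter; it follows the model defaults except for the descending-D
#' double-well condition, which uses `u = -4`: with the default `u = 0` the
#' upper equilibrium persists down to `D = 0` (the coupling input is
#' non-negative), so no collapse would ever occur. A uniform negative
#' stress below the isolated-node fold (at about `u = -3.08`) makes the
#' upper branch depend on coupling and restores a tipping point.
#'
#' @return A data frame with columns `model_id`, `control`, `direction`,
#'   `low`, `high`, `fixed_value`.
#' @export
lattice_conditions <- function() {
  cond <- enumerate_conditions()
  cond$low  <- c(0,    -4.5, 0,    0.02, -4,  0.02, 0.05, 0.05, -2,  0.1)
  cond$high <- c(3.2,  0,    0.55, 1,    0,   1,    0.35, 1,    0,   1)
  cond$fixed_value <- c(0.05, 0.05, 0, -4, 0.05, -5, NA, NA, 1, 0)
  cond
}

## model_spec for one condition row, honouring a fixed_value override.
condition_spec <- function(row) {
  fv <- row$fixed_value
  model_spec(row$model_id, control = row$control,
             fixed_value = if (is.null(fv) || is.na(fv)) NULL else fv)
}

#' Evaluate all six EWSs on one sweep
#'
#' Glues the pieces together for a single sweep: extracts the home range,
#' computes the six EWS series, and scores each with the sign-adjusted
#' Kendall tau over the latter half of the home range and the slope-ratio
#' classification.
#'
#' @param result A [run_sweep()] result.
#' @param net The network the sweep ran on.
#' @param theta Slope-ratio threshold for [classify_ews()] (default 2).
#' @return A data frame with one row per EWS: `ews_id`, `tau`, `tau_prime`,
#'   `slope_a`, `slope_b`, `category`, `home_range_k`, `n_latter_half`.
#' @export
evaluate_sweep <- function(result, net, theta = 2) {
  k <- find_home_range(result)
  ews <- suppressWarnings(compute_ews(result, net))
  direction <- result$cfg$direction
  rows <- lapply(EWS_IDS, function(id) {
    v <- ews[[id]]
    tp <- tryCatch(kendall_tau_prime(result$param_grid, v, k, direction),
                   error = function(e) list(tau = NA_real_,
                                            tau_prime = NA_real_,
                                            n_points = 0L))
    cl <- tryCatch(classify_ews(result$param_grid, v, k, theta = theta),
                   error = function(e) list(slope_a = NA_real_,
                                            slope_b = NA_real_,
                                            category = "undetermined"))
    data.frame(ews_id = id, tau = tp$tau, tau_prime = tp$tau_prime,
               slope_a = cl$slope_a, slope_b = cl$slope_b,
               category = cl$category, home_range_k = k,
               n_latter_half = tp$n_points, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run an experiment over conditions x networks
#'
#' Runs every (condition, network) cell end to end: sweep, home range, six
#' EWS series, tau-prime and classification per EWS. Failures of individual
#' cells (e.g. a sweep whose range contains no tipping point) are recorded
#' in the `status` column and do not abort the experiment.
#'
#' @param manifest A list with elements:
#'   `conditions` (data frame with `model_id`, `control`, `direction`,
#'   `low`, `high` and optionally `fixed_value`), `networks` (named list of
#'   igraph networks), and optional `L` (default 100), `dt` (0.01),
#'   `t_equil` (50), `seed` (1), `theta` (2).
#' @return A data frame with one row per (condition, network, EWS):
#'   condition columns, `network`, `seed`, the [evaluate_sweep()] columns
#'   and `status` (`"ok"`, `"no_tipping"` or `"error: ..."`).
#' @export
run_experiment <- function(manifest) {
  cond <- manifest$conditions
  nets <- manifest$networks
  if (is.null(names(nets)) || any(names(nets) == ""))
    stop("manifest$networks must be a named list")
  L <- manifest$L %||% 100
  dt <- manifest$dt %||% 0.01
  t_equil <- manifest$t_equil %||% 50
  seed <- manifest$seed %||% 1
  theta <- manifest$theta %||% 2
  out <- list(); cell <- 0L
  for (ci in seq_len(nrow(cond))) {
    for (nm in names(nets)) {
      cell <- cell + 1L
      row <- cond[ci, , drop = FALSE]
      cell_seed <- child_seed(seed, cell)
      res <- tryCatch({
        spec <- condition_spec(row)
        cfg <- sweep_config(c(row$low, row$high), row$direction, L = L,
                            dt = dt, t_equil = t_equil, seed = cell_seed)
        sw <- run_sweep(spec, nets[[nm]], cfg)
        ev <- evaluate_sweep(sw, nets[[nm]], theta = theta)
        ev$status <- "ok"
        ev
      }, error = function(e) {
        status <- if (grepl("tipping", conditionMessage(e)))
          "no_tipping" else paste0("error: ", conditionMessage(e))
        data.frame(ews_id = EWS_IDS, tau = NA_real_, tau_prime = NA_real_,
                   slope_a = NA_real_, slope_b = NA_real_,
                   category = NA_character_, home_range_k = NA_integer_,
                   n_latter_half = NA_integer_, status = status,
                   stringsAsFactors = FALSE)
      })
      meta <- data.frame(model_id = row$model_id, control = row$control,
                         direction = row$direction, network = nm,
                         seed = cell_seed, stringsAsFactors = FALSE)
      out[[cell]] <- cbind(meta[rep(1, nrow(res)), , drop = FALSE], res)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reproduce the square-lattice experiment
#'
#' Runs all ten retained simulation conditions on the 10 x 10 periodic
#' square lattice (N = 100) with the shipped simulation ranges
#' ([lattice_conditions()]), the default model parameters and the standard
#' sweep protocol (L = 100 grid points, dt = 0.01, 50 time units per grid
#' point), then summarizes each EWS by the number of conditions in which it
#' is classified successful (accelerating or reversing) and its mean
#' tau-prime over that successful subset.
#'
#' @param master_seed Integer master seed; condition-level seeds are derived
#'   from it deterministically.
#' @param L,dt,t_equil Sweep protocol settings (defaults 100, 0.01, 50).
#' @param theta Slope-ratio classification threshold (default 2).
#' @return A list with `results` (the full per-condition, per-EWS table as
#'   from [run_experiment()]) and `summary` (one row per EWS: `ews_id`,
#'   `n_success` out of 10, `mean_tau_prime_success`).
#' @export
reproduce_lattice_experiment <- function(master_seed = 1, L = 100, dt = 0.01,
                                         t_equil = 50, theta = 2) {
  net <- make_periodic_lattice(10)
  manifest <- list(conditions = lattice_conditions(),
                   networks = list(lattice = net),
                   L = L, dt = dt, t_equil = t_equil,
                   seed = master_seed, theta = theta)
  results <- run_experiment(manifest)
  summary <- do.call(rbind, lapply(EWS_IDS, function(id) {
    sub <- results[results$ews_id == id & results$status == "ok", ]
    succ <- sub$category %in% c("accelerating", "reversing")
    data.frame(ews_id = id, n_success = sum(succ),
               mean_tau_prime_success = if (any(succ))
                 mean(sub$tau_prime[succ]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(results = results, summary = summary)
}
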