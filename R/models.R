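## The four stochastic dynamics models: drift fields, default parameters,
## initial states and lower/upper node-state rules.

MODEL_IDS <- c("double_well", "mutualistic", "sis", "gene")

#' Default parameter record of a dynamics model
#'
#' Returns the standard parameter values used throughout:
#' * `double_well`: equilibrium positions `r1 = 1 < r2 = 3 < r3 = 5`;
#' * `mutualistic`: migration `B = 0.1`, carrying capacity `K = 5`, Allee
#'   constant `C = 1`, interaction saturation `Dt = 5`, `E = 0.9`, `H = 0.1`;
#' * `sis`: recovery rate `mu = 1`;
#' * `gene`: degradation `B = 1`, exponent `f = 1`, Hill coefficient `h = 2`.
#'
#' @param model_id One of `"double_well"`, `"mutualistic"`, `"sis"`, `"gene"`.
#' @return Named list of parameters.
#' @export
default_params <- function(model_id) {
  switch(match.arg(model_id, MODEL_IDS),
    double_well = list(r1 = 1, r2 = 3, r3 = 5),
    mutualistic = list(B = 0.1, K = 5, C = 1, Dt = 5, E = 0.9, H = 0.1),
    sis         = list(mu = 1),
    gene        = list(B = 1, f = 1, h = 2))
}

default_sigma <- function(model_id) {
  switch(match.arg(model_id, MODEL_IDS),
    double_well = 0.1, mutualistic = 0.001, sis = 0.001, gene = 0.001)
}

## Default value of the non-control parameter: D when u is swept, u when D is.
default_fixed_value <- function(model_id, control) {
  if (model_id == "sis") return(NA_real_)  # the SIS model has no u
  if (control == "u") {
    switch(model_id, double_well = 0.05, mutualistic = 0.05, gene = 1)
  } else {
    switch(model_id, double_well = 0, mutualistic = -5, gene = 0)
  }
}

#' Specify a dynamics model and its control parameter
#'
#' Bundles a model identity with its parameter record, noise strength, the
#' identity of the control parameter (coupling strength `D` or uniform stress
#' `u`) and the fixed value of the non-control parameter.
#'
#' @param model_id One of `"double_well"`, `"mutualistic"`, `"sis"`, `"gene"`.
#' @param control `"D"` or `"u"`. The SIS model admits only `"D"` (the
#'   infection rate); a uniform stress has no epidemiological meaning there.
#' @param params Parameter record; defaults to [default_params()]. For the
#'   double-well model `r1 < r2 < r3` is required.
#' @param sigma Noise strength (standard deviation of the Gaussian forcing);
#'   defaults to 0.1 for the double-well model and 0.001 otherwise.
#' @param fixed_value Value of the non-control parameter (`u` when sweeping
#'   `D`, `D` when sweeping `u`); defaults per model.
#' @return An object of class `"model_spec"`.
#' @examples
#' spec <- model_spec("double_well", control = "u")
#' spec$params$r2
#' @export
model_spec <- function(model_id, control = c("D", "u"), params = NULL,
                       sigma = NULL, fixed_value = NULL) {
  model_id <- match.arg(model_id, MODEL_IDS)
  control <- match.arg(control)
  if (model_id == "sis" && control != "D")
    stop("the SIS model has no stress parameter u; control must be \"D\"")
  if (is.null(params)) params <- default_params(model_id)
  defaults <- default_params(model_id)
  missing_p <- setdiff(names(defaults), names(params))
  if (length(missing_p))
    stop("missing parameters for ", model_id, ": ",
         paste(missing_p, collapse = ", "))
  if (!all(vapply(params, function(v) is.numeric(v) && is.finite(v), TRUE)))
    stop("all model parameters must be finite numbers")
  if (model_id == "double_well" &&
      !(params$r1 < params$r2 && params$r2 < params$r3))
    stop("double_well parameters must satisfy r1 < r2 < r3")
  if (is.null(sigma)) sigma <- default_sigma(model_id)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("`sigma` must be a finite non-negative number")
  if (is.null(fixed_value)) fixed_value <- default_fixed_value(model_id, control)
  structure(list(model_id = model_id, control = control, params = params,
                 sigma = sigma, fixed_value = fixed_value),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$model_id, "  control = ", x$control,
      "  sigma = ", x$sigma, "\n", sep = "")
  cat("  params: ",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      "\n", sep = "")
  if (!is.na(x$fixed_value))
    cat("  fixed ", if (x$control == "D") "u" else "D", " = ",
        x$fixed_value, "\n", sep = "")
  invisible(x)
}

## (D, u) pair for a given control-parameter value.
resolve_Du <- function(spec, value) {
  if (spec$control == "D") {
    list(D = value, u = if (is.na(spec$fixed_value)) 0 else spec$fixed_value)
  } else {
    list(D = spec$fixed_value, u = value)
  }
}

#' Deterministic drift field of a dynamics model
#'
#' Evaluates the drift (the deterministic part of `dx_i/dt`) at a state
#' vector on a network:
#' * double-well: `-(x_i - r1)(x_i - r2)(x_i - r3) + D * sum_j A_ij x_j + u`
#' * mutualistic: `B + x_i (1 - x_i/K)(x_i/C - 1) +
#'   D * sum_j A_ij x_i x_j / (Dt + E x_i + H x_j) + u`
#' * SIS: `-mu x_i + D * sum_j A_ij (1 - x_i) x_j`
#' * gene: `-B x_i^f + D * sum_j A_ij x_j^h / (1 + x_j^h) + u`
#'
#' @param spec A [model_spec()].
#' @param x Finite numeric state vector, one entry per node.
#' @param net Network with `length(x)` nodes.
#' @param D Coupling strength (infection rate for SIS), `D >= 0`.
#' @param u Uniform stress; ignored for the SIS model.
#' @return Numeric vector of drifts, one per node.
#' @export
drift <- function(spec, x, net, D, u = 0) {
  stopifnot(inherits(spec, "model_spec"))
  if (!all(is.finite(x))) stop("state vector `x` must be finite")
  if (!is.finite(D) || D < 0) stop("`D` must be finite and >= 0")
  assert_network(net)
  if (igraph::vcount(net) != length(x))
    stop("length(x) must equal the number of nodes")
  A <- adjacency(net)
  p <- spec$params
  switch(spec$model_id,
    double_well = -(x - p$r1) * (x - p$r2) * (x - p$r3) +
      D * as.numeric(A %*% x) + u,
    mutualistic = {
      pair <- outer(x, x) / (p$Dt + p$E * x + p$H * rep(x, each = length(x)))
      ## pair[i, j] = x_i x_j / (Dt + E x_i + H x_j)
      p$B + x * (1 - x / p$K) * (x / p$C - 1) +
        D * rowSums(A * pair) + u
    },
    sis = -p$mu * x + D * (1 - x) * as.numeric(A %*% x),
    gene = {
      if (p$f != round(p$f) && any(x < 0))
        stop("gene drift undefined for negative state with fractional exponent f")
      hill <- x^p$h / (1 + x^p$h)
      -p$B * x^p$f + D * as.numeric(A %*% hill) + u
    })
}

#' Classify a node state as lower or upper
#'
#' Applies the per-model threshold: double-well nodes are lower when
#' `x < r2`; mutualistic nodes are lower when `x <= C` (the Allee threshold
#' separating collapse from persistence); SIS and gene-regulatory nodes are
#' lower when `x < 5 * sigma`, i.e. indistinguishable from the extinct state
#' at the resolution of the noise.
#'
#' @param spec A [model_spec()].
#' @param x Numeric vector of node states.
#' @return Character vector over `"lower"` / `"upper"`.
#' @export
classify_node_state <- function(spec, x) {
  stopifnot(inherits(spec, "model_spec"))
  if (!all(is.finite(x))) stop("state must be finite")
  lower <- switch(spec$model_id,
    double_well = x < spec$params$r2,
    mutualistic = x <= spec$params$C,
    sis = x < 5 * spec$sigma,
    gene = x < 5 * spec$sigma)
  ifelse(lower, "lower", "upper")
}

#' Initial state of a sweep
#'
#' Ascending sweeps start in the lower state, descending sweeps in the upper
#' state. The mutualistic and gene-regulatory models are only simulated
#' descending (collapse of the extant/active state); requesting an ascending
#' sweep for them is an error.
#'
#' @param spec A [model_spec()].
#' @param direction `"ascending"` or `"descending"`.
#' @param n Number of nodes.
#' @return Constant numeric vector of length `n`: double-well `r1` / `r3`;
#'   SIS 0.001 / 0.999; mutualistic 6 (descending only); gene 2 (descending
#'   only).
#' @export
initial_state <- function(spec, direction = c("ascending", "descending"), n) {
  stopifnot(inherits(spec, "model_spec"))
  direction <- match.arg(direction)
  val <- switch(spec$model_id,
    double_well = if (direction == "ascending") spec$params$r1 else spec$params$r3,
    mutualistic = if (direction == "descending") 6 else
      stop("the mutualistic model supports descending sweeps only ",
           "(collapse from the extant state)"),
    sis = if (direction == "ascending") 0.001 else 0.999,
    gene = if (direction == "descending") 2 else
      stop("the gene-regulatory model supports descending sweeps only ",
           "(loss of the active state)"))
  rep(val, n)
}

## Models whose states are clamped at zero after every integration step
## (negative abundance/probability/expression is unphysical). The
## double-well state is a generic coordinate and is never clamped.
model_clamps <- function(model_id) model_id != "double_well"
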