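## Euler-Maruyama integration front end.

#' Integrate a dynamics model by the Euler-Maruyama method
#'
#' Iterates `x <- x + drift(x) * dt + sigma * sqrt(dt) * z` with `z`
#' independent standard normal per node per step. For the mutualistic, SIS
#' and gene-regulatory models any component pushed below zero is reset to
#' zero immediately after each step (negative abundance, probability or
#' expression is unphysical); the double-well state is never clamped. Noise
#' comes from R's RNG, so results are reproducible under [set.seed()].
#'
#' @param spec A [model_spec()].
#' @param net Network the dynamics run on.
#' @param D,u Coupling strength and uniform stress at which to integrate
#'   (`u` is ignored for the SIS model).
#' @param x0 Initial state vector, one finite value per node.
#' @param dt Step size (default 0.01).
#' @param t_end Integration horizon in time units (default 50); `t_end / dt`
#'   must be an integer to within rounding.
#' @return The state vector after `round(t_end / dt)` steps.
#' @examples
#' net <- make_periodic_lattice(3)
#' spec <- model_spec("double_well", control = "u", sigma = 0)
#' integrate_em(spec, net, D = 0, u = 0, x0 = rep(5, 9))
#' @export
integrate_em <- function(spec, net, D, u = 0, x0, dt = 0.01, t_end = 50) {
  stopifnot(inherits(spec, "model_spec"))
  assert_network(net)
  n <- igraph::vcount(net)
  if (length(x0) != n) stop("length(x0) must equal the number of nodes")
  if (!all(is.finite(x0))) stop("`x0` must be finite")
  if (!is.finite(D) || D < 0) stop("`D` must be finite and >= 0")
  if (dt <= 0) stop("`dt` must be positive")
  nsteps <- round(t_end / dt)
  if (abs(t_end / dt - nsteps) > 1e-8)
    stop("`t_end` must be an integer multiple of `dt`")
  ee <- edge_ends0(net)
  model <- match(spec$model_id, MODEL_IDS) - 1L
  params <- unlist(default_order_params(spec))
  .em_integrate_cpp(model, params, ee$from, ee$to, as.numeric(x0),
                    D, u, dt, as.integer(nsteps), spec$sigma,
                    model_clamps(spec$model_id))
}

## Parameters in the positional order the compiled kernel expects.
default_order_params <- function(spec) {
  p <- spec$params
  switch(spec$model_id,
    double_well = p[c("r1", "r2", "r3")],
    mutualistic = p[c("B", "K", "C", "Dt", "E", "H")],
    sis         = p["mu"],
    gene        = p[c("B", "f", "h")])
}
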