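## Synthetic EWS curves: archetypal trajectories used to exercise the
## classifier independently of any simulation.

CURVE_ARCHETYPES <- c("accelerating", "reversing",
                      "unsuccessful_early_rise", "unsuccessful_flat")

#' Generate a synthetic EWS curve of a named archetype
#'
#' Produces an idealized EWS trajectory over an ascending unit parameter
#' grid, optionally with additive Gaussian noise. The noise-free shapes are
#' built so that [classify_ews()] with `theta = 2` (over the full curve)
#' returns the category the archetype names:
#' * `accelerating`: convex rise `t^3` — small positive early slope, much
#'   larger late slope;
#' * `reversing`: `(t - 0.3)^2` — early decline, late rise;
#' * `unsuccessful_early_rise`: `1 - exp(-10 t)` — fast early rise, then a
#'   plateau (false positive early, false negative late);
#' * `unsuccessful_flat`: gentle linear decline, never rising.
#'
#' @param archetype One of `"accelerating"`, `"reversing"`,
#'   `"unsuccessful_early_rise"`, `"unsuccessful_flat"`.
#' @param L_points Number of grid points, at least 10.
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (default 0).
#' @param seed Integer seed for the noise.
#' @return An object of class `"ews_curve"`: list with `param_values`
#'   (strictly increasing), `values`, `archetype`, `noise_sd`, `seed`.
#' @examples
#' cu <- make_ews_curve("reversing", 40)
#' classify_ews(cu$param_values, cu$values, home_range = 40)$category
#' @export
make_ews_curve <- function(archetype, L_points, noise_sd = 0, seed = 1) {
  archetype <- match.arg(archetype, CURVE_ARCHETYPES)
  L_points <- as.integer(L_points)
  if (L_points < 10) stop("`L_points` must be at least 10")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  t <- seq(0, 1, length.out = L_points)
  y <- switch(archetype,
    accelerating = t^3,
    reversing = (t - 0.3)^2,
    unsuccessful_early_rise = 1 - exp(-10 * t),
    unsuccessful_flat = 0.2 - 0.05 * t)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    y <- y + stats::rnorm(L_points, sd = noise_sd)
  }
  structure(list(param_values = t, values = y, archetype = archetype,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ews_curve")
}
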