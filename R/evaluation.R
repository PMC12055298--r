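## Scoring an EWS series over a home range: sign-adjusted Kendall tau and
## the accelerating / reversing / unsuccessful classification.

#' Sign-adjusted Kendall rank correlation over the latter half of the home range
#'
#' Restricts the series to the last `ceiling(k/2)` home-range points (the
#' half nearest the tipping point), computes the Kendall rank correlation
#' `tau` between the control-parameter values and the EWS values (tau-b,
#' tie-corrected), and applies the direction sign rule: `tau' = tau` for
#' ascending sweeps and `tau' = -tau` for descending sweeps, so that a
#' larger `tau'` always means "the EWS grows as the tipping point nears".
#'
#' @param param_grid Control-parameter values in traversal order.
#' @param ews_values EWS values aligned to `param_grid` (may contain `NA`).
#' @param home_range Number of leading grid points in the home range
#'   (e.g. from [find_home_range()]); must be at least 4.
#' @param direction `"ascending"` or `"descending"`.
#' @return A list with `tau`, `tau_prime` and `n_points` (non-missing points
#'   used).
#' @export
kendall_tau_prime <- function(param_grid, ews_values, home_range,
                              direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  k <- as.integer(home_range)
  if (k < 4) stop("home range too short for tau (need k >= 4)")
  if (k > length(param_grid)) stop("home range exceeds the grid")
  idx <- seq.int(k - ceiling(k / 2) + 1L, k)
  p <- param_grid[idx]; v <- ews_values[idx]
  ok <- is.finite(p) & is.finite(v)
  if (sum(ok) < 3)
    stop("tau is undefined: fewer than 3 non-missing EWS values in the ",
         "latter half of the home range")
  tau <- suppressWarnings(stats::cor(p[ok], v[ok], method = "kendall"))
  if (is.na(tau))
    stop("tau is undefined: a tied-constant series in the latter half")
  list(tau = tau,
       tau_prime = if (direction == "ascending") tau else -tau,
       n_points = sum(ok))
}

#' Classify an EWS trajectory as accelerating, reversing or unsuccessful
#'
#' Fits ordinary least-squares slopes of the EWS on the control parameter
#' over the first five home-range points (`a`, the trend far from the
#' tipping point) and the last five (`b`, the trend near it). For
#' descending sweeps the regressor is the negated control parameter, so that
#' "increasing toward the tipping point" is a positive slope in both
#' directions; the traversal direction is inferred from the order of
#' `param_grid`. The categories are:
#' * accelerating: `a > 0`, `b > 0` and `b / a > theta`;
#' * reversing: `a < 0`, `b > 0` and `|b / a| > 0.5 * theta`;
#' * unsuccessful: anything else.
#'
#' @param param_grid Control-parameter values in traversal order.
#' @param ews_values EWS values aligned to `param_grid`.
#' @param home_range Number of leading home-range points; must be at least
#'   10 so the two five-point windows are disjoint, otherwise a
#'   classification-undetermined error (distinct from "unsuccessful") is
#'   raised. Each window must contain five non-missing values.
#' @param theta Slope-ratio threshold, greater than 1 (default 2).
#' @return An object of class `"ews_classification"`: list with `slope_a`,
#'   `slope_b`, `category`, `theta`.
#' @examples
#' p <- seq(0, 1, length.out = 40)
#' classify_ews(p, p^3, home_range = 40)   # accelerating
#' @export
classify_ews <- function(param_grid, ews_values, home_range, theta = 2) {
  if (!is.numeric(theta) || theta <= 1) stop("`theta` must be > 1")
  k <- as.integer(home_range)
  if (k > length(param_grid)) stop("home range exceeds the grid")
  if (k < 10)
    stop("classification undetermined: home range k = ", k, " < 10, the ",
         "first-5 and last-5 regression windows would overlap")
  dp <- diff(param_grid)
  if (all(dp > 0)) oriented <- param_grid
  else if (all(dp < 0)) oriented <- -param_grid
  else stop("`param_grid` must be strictly monotone in traversal order")
  slope5 <- function(idx) {
    p <- oriented[idx]; v <- ews_values[idx]
    ok <- is.finite(v)
    if (sum(ok) < 5)
      stop("classification undetermined: fewer than 5 non-missing EWS ",
           "values in a regression window")
    unname(coef(stats::lm(v ~ p))[2])
  }
  a <- slope5(1:5)
  b <- slope5((k - 4L):k)
  category <- if (a > 0 && b > 0 && b / a > theta) "accelerating"
  else if (a < 0 && b > 0 && abs(b / a) > 0.5 * theta) "reversing"
  else "unsuccessful"
  structure(list(slope_a = a, slope_b = b, category = category,
                 theta = theta),
            class = "ews_classification")
}

#' @export
print.ews_classification <- function(x, ...) {
  cat("<ews_classification> ", x$category,
      "  (a = ", format(x$slope_a, digits = 4),
      ", b = ", format(x$slope_b, digits = 4),
      ", theta = ", x$theta, ")\n", sep = "")
  invisible(x)
}

#' Fraction of successful classifications
#'
#' An EWS counts as successful when classified accelerating or reversing.
#'
#' @param classifications A list of [classify_ews()] results, or a character
#'   vector of categories.
#' @return Fraction in `[0, 1]`.
#' @export
success_fraction <- function(classifications) {
  if (length(classifications) == 0) stop("empty classification list")
  cats <- if (is.character(classifications)) classifications
  else vapply(classifications, function(cl) cl$category, character(1))
  mean(cats %in% c("accelerating", "reversing"))
}

#' Rank-score EWSs across simulation conditions
#'
#' Within each condition the six EWSs are ranked by the metric (larger is
#' better): the best receives 5 points, the second best 4, down to 0 for the
#' worst; ties receive the average of the tied scores (two EWSs tied for
#' best get 4.5 each). Scores are summed across conditions, so the six
#' totals always add up to `15 * C`.
#'
#' @param per_condition_metric A 6 x C numeric matrix (rows: EWSs, columns:
#'   conditions), e.g. of per-condition success fractions.
#' @return Named numeric vector of total scores, one per EWS row.
#' @export
rank_scores <- function(per_condition_metric) {
  m <- as.matrix(per_condition_metric)
  if (nrow(m) != 6) stop("expected 6 EWS rows, got ", nrow(m))
  if (ncol(m) < 1) stop("need at least one condition column")
  if (!all(is.finite(m))) stop("metric values must be finite")
  scores <- apply(m, 2, function(col) rank(col, ties.method = "average") - 1)
  total <- rowSums(scores)
  names(total) <- rownames(m)
  total
}
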