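## The six single-snapshot spatial early warning signals.
##
## All six are computed from one snapshot of node states x* (one sample per
## node): Moran's I, spatial standard deviation, spatial variance (second
## central moment), coefficient of variation, sign-adjusted skewness and
## kurtosis. Moran's I is the only one that also needs the adjacency matrix.

EWS_IDS <- c("moran_i", "spatial_sd", "spatial_var", "cv",
             "skewness_adj", "kurtosis")

#' Moran's I spatial autocorrelation on a graph
#'
#' `I_M = (N / W) * sum_ij A_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `W = sum_ij A_ij` (twice the edge count). Close to 1 when adjacent
#' nodes have similar states, close to -1 when dissimilar, near 0 when
#' uncorrelated; it can fall outside `[-1, 1]`.
#'
#' @param x Numeric state vector, one value per node; must not be constant.
#' @param net Network on whose adjacency the statistic is computed.
#' @return Moran's I.
#' @examples
#' net <- make_periodic_lattice(3)
#' morans_i(rnorm(9), net)
#' @export
morans_i <- function(x, net) {
  assert_network(net)
  n <- length(x)
  if (igraph::vcount(net) != n) stop("length(x) must equal the number of nodes")
  if (n < 2) stop("need at least 2 nodes")
  d <- x - mean(x)
  denom <- sum(d^2)
  if (denom == 0)
    stop("Moran's I is undefined for a constant state (zero variance)")
  ee <- edge_ends0(net)
  W <- 2 * length(ee$from)
  num <- 2 * sum(d[ee$from + 1L] * d[ee$to + 1L])
  (n / W) * num / denom
}

#' Spatial standard deviation
#'
#' The unbiased sample standard deviation of the node states,
#' `s = sqrt(sum (x_i - xbar)^2 / (N - 1))`.
#'
#' @param x Numeric state vector of length at least 2.
#' @return The sample standard deviation.
#' @export
spatial_sd <- function(x) {
  if (length(x) < 2) stop("need at least 2 nodes")
  stats::sd(x)
}

#' Central moments of a state snapshot
#'
#' `m_k = sum (x_i - xbar)^k / N` (note the `N`, not `N - 1`, denominator:
#' `m_2` is therefore a distinct statistic from `spatial_sd(x)^2`, and both
#' are kept as separate EWSs).
#'
#' @param x Numeric state vector.
#' @param k Moment order, a positive integer.
#' @return The k-th central moment.
#' @export
central_moment <- function(x, k) {
  if (length(x) < 1 || k < 1) stop("need length(x) >= 1 and k >= 1")
  mean((x - mean(x))^k)
}

#' Spatial coefficient of variation
#'
#' `CV = s / xbar`, the spatial standard deviation normalized by the signed
#' spatial mean. Undefined when the mean is (numerically) zero.
#'
#' @param x Numeric state vector of length at least 2.
#' @param tol Mean magnitudes below `tol` raise an undefined-statistic
#'   error (default `1e-12`).
#' @return The coefficient of variation.
#' @export
spatial_cv <- function(x, tol = 1e-12) {
  m <- mean(x)
  if (abs(m) < tol)
    stop("CV is undefined: spatial mean is zero (within tolerance)")
  spatial_sd(x) / m
}

#' Spatial skewness and its sign adjustment
#'
#' `g1 = m_3 / m_2^(3/2)`; it approaches 0 for a symmetric distribution as
#' N grows. Because a useful warning may show up as increasingly negative
#' skew in descending sweeps, the EWS actually scored is
#' `g1' = g1` for ascending sweeps and `g1' = -g1` for descending ones, so
#' that "larger = stronger warning" holds in both directions.
#'
#' @param x Numeric state vector with positive variance.
#' @param g1 A skewness value.
#' @param direction `"ascending"` or `"descending"`.
#' @return `spatial_skewness`: g1. `sign_adjust_skewness`: g1'.
#' @export
spatial_skewness <- function(x) {
  m2 <- central_moment(x, 2)
  if (m2 == 0) stop("skewness is undefined for zero variance")
  central_moment(x, 3) / m2^1.5
}

#' @rdname spatial_skewness
#' @export
sign_adjust_skewness <- function(g1, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  if (direction == "ascending") g1 else -g1
}

#' Spatial kurtosis
#'
#' `g2 = m_4 / m_2^2`, the raw (not excess) sample kurtosis; it approaches
#' 3 for a normal distribution as N grows. No `-3` adjustment is applied.
#'
#' @param x Numeric state vector with positive variance.
#' @return The sample kurtosis.
#' @export
spatial_kurtosis <- function(x) {
  m2 <- central_moment(x, 2)
  if (m2 == 0) stop("kurtosis is undefined for zero variance")
  central_moment(x, 4) / m2^2
}

#' Compute all six EWSs along a sweep
#'
#' Evaluates each EWS on every grid row's snapshot (one sample per node).
#' Rows where a statistic is undefined (constant states for Moran's I,
#' skewness and kurtosis; zero mean for CV) are recorded as `NA`, not
#' dropped; a warning reports how many values were missing.
#'
#' @param result A [run_sweep()] result.
#' @param net The network the sweep ran on (needed for Moran's I).
#' @return A data frame with one row per grid point and columns
#'   `param_index`, `param_value` and the six EWS ids (`moran_i`,
#'   `spatial_sd`, `spatial_var`, `cv`, `skewness_adj`, `kurtosis`), with
#'   attribute `direction`.
#' @export
compute_ews <- function(result, net) {
  stopifnot(inherits(result, "sweep_result"))
  assert_network(net)
  L <- result$cfg$L
  direction <- result$cfg$direction
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  out <- data.frame(param_index = seq_len(L),
                    param_value = result$param_grid,
                    moran_i = NA_real_, spatial_sd = NA_real_,
                    spatial_var = NA_real_, cv = NA_real_,
                    skewness_adj = NA_real_, kurtosis = NA_real_)
  for (i in seq_len(L)) {
    x <- result$states[i, ]
    out$moran_i[i] <- safe(morans_i(x, net))
    out$spatial_sd[i] <- safe(spatial_sd(x))
    out$spatial_var[i] <- safe(central_moment(x, 2))
    out$cv[i] <- safe(spatial_cv(x))
    out$skewness_adj[i] <- safe(sign_adjust_skewness(spatial_skewness(x),
                                                     direction))
    out$kurtosis[i] <- safe(spatial_kurtosis(x))
  }
  n_missing <- sum(is.na(out[EWS_IDS]))
  if (n_missing > 0)
    warning(n_missing, " undefined EWS value(s) recorded as missing")
  attr(out, "direction") <- direction
  out
}

#' Write an EWS table in long CSV form
#'
#' Columns `param_index`, `param_value`, `ews_id`, `value`; missing values
#' are written as empty fields.
#'
#' @param ews_table A [compute_ews()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ews_csv <- function(ews_table, path) {
  long <- do.call(rbind, lapply(EWS_IDS, function(id)
    data.frame(param_index = ews_table$param_index,
               param_value = ews_table$param_value,
               ews_id = id, value = ews_table[[id]])))
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}
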