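# Point-pattern statistics: Delaunay inter-particle distances, the
# nearest-particle G-function with CSR envelopes, distribution-free median
# confidence intervals, KS tests and cross-modality scale ratios.

#' Delaunay inter-particle distances
#'
#' Lengths of the unique edges of the Delaunay triangulation of the points.
#' The triangulation links each particle only to its natural neighbours,
#' discarding the long-range pairings an all-pairs distance listing would
#' include.
#'
#' @param points Data frame with `x`, `y` (nm); >= 3 non-collinear points.
#' @return Numeric vector of edge lengths in nm.
#' @export
delaunay_edge_distances <- function(points) {
  xy <- as_xy(points)
  nt_delaunay(xy$x, xy$y)$edges$length
}

#' Nearest-particle distance function G(d)
#'
#' Empirical cumulative distribution of nearest-particle distances:
#' `G(d) = (1/n) * sum_i I(d_min(p_i) < d)` with strict inequality, where
#' `d_min(p_i)` is the distance from particle i to its nearest other
#' particle. No edge correction is applied.
#'
#' @param points Data frame with `x`, `y` (nm); at least 2 points.
#' @param d_grid Distance grid in nm; defaults to 256 evenly spaced values
#'   from 0 to the 99th percentile of the nearest-neighbour distances.
#' @return An `nt_gfunction`: tibble with columns `d`, `G` and attributes
#'   `nn_dist` (the per-point nearest distances) and `n_points`.
#' @export
g_function <- function(points, d_grid = NULL) {
  xy <- as_xy(points)
  if (length(xy$x) < 2) abort("G(d) needs at least 2 points",
                              class = "nt_invalid_parameter")
  dmin <- nt_nn_dist(xy$x, xy$y)
  d_grid <- d_grid %||% seq(0, stats::quantile(dmin, 0.99, names = FALSE),
                            length.out = 256)
  G <- vapply(d_grid, function(d) mean(dmin < d), numeric(1))
  out <- tibble(d = d_grid, G = G)
  structure(out, nn_dist = dmin, n_points = length(xy$x),
            class = c("nt_gfunction", class(out)))
}

#' Pointwise CSR envelopes for G(d)
#'
#' Simulates `n_simulations` complete-spatial-randomness patterns matched in
#' point count and region and returns the pointwise 2.5% and 97.5% quantiles
#' of their G functions on the grid: the 95% confidence band under CSR.
#'
#' @param region An `nt_region`.
#' @param n_points Points per simulated pattern.
#' @param d_grid Distance grid in nm.
#' @param n_simulations Number of CSR patterns (default 99).
#' @param seed Integer seed.
#' @return Tibble with columns `d`, `envelope_low`, `envelope_high`.
#' @export
csr_envelope <- function(region, n_points, d_grid, n_simulations = 99,
                         seed = NULL) {
  if (n_simulations < 1) abort("n_simulations must be >= 1",
                               class = "nt_invalid_parameter")
  if (!is.null(seed)) set.seed(seed)
  sims <- matrix(NA_real_, n_simulations, length(d_grid))
  for (s in seq_len(n_simulations)) {
    p <- region_sample(region, n_points)
    dmin <- nt_nn_dist(p$x, p$y)
    sims[s, ] <- vapply(d_grid, function(d) mean(dmin < d), numeric(1))
  }
  lo <- apply(sims, 2, stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(sims, 2, stats::quantile, probs = 0.975, names = FALSE)
  tibble(d = d_grid, envelope_low = lo, envelope_high = hi)
}

#' G(d) with CSR envelopes
#'
#' Convenience wrapper: computes [g_function()] of the data and the matched
#' [csr_envelope()] on the same grid, joined into one result.
#'
#' @inheritParams g_function
#' @param region Region for the CSR simulations (defaults to the attribute
#'   attached by the simulator or the bounding box).
#' @param n_simulations CSR patterns (default 99).
#' @param seed Integer seed.
#' @return An `nt_gfunction` tibble with columns `d`, `G`, `envelope_low`,
#'   `envelope_high`.
#' @export
g_function_csr <- function(points, region = NULL, d_grid = NULL,
                           n_simulations = 99, seed = NULL) {
  region <- region %||% attr(points, "region") %||% bbox_region(points)
  g <- g_function(points, d_grid)
  env <- csr_envelope(region, attr(g, "n_points"), g$d, n_simulations, seed)
  out <- dplyr::left_join(as_tibble(g), env, by = "d")
  structure(out, nn_dist = attr(g, "nn_dist"),
            n_points = attr(g, "n_points"),
            class = c("nt_gfunction", class(out)))
}

#' Maximum distance of considerable clustering
#'
#' Clustering is declared where G(d) exceeds the upper CSR envelope. The
#' statistic is the largest distance of the contiguous exceedance run that
#' starts at the smallest exceeding grid point; `NA` when G never leaves the
#' envelope (no detectable clustering).
#'
#' @param result An `nt_gfunction` with envelope columns.
#' @return Distance in nm, or `NA_real_`.
#' @export
max_clustering_distance <- function(result) {
  stopifnot(all(c("G", "envelope_high") %in% names(result)))
  exceed <- result$G > result$envelope_high
  if (!any(exceed)) return(NA_real_)
  first <- which(exceed)[1]
  run_end <- first
  while (run_end < length(exceed) && exceed[run_end + 1]) run_end <- run_end + 1
  result$d[run_end]
}

#' Distribution-free median confidence interval
#'
#' Median with a confidence interval from binomial order statistics: the
#' lower rank is the `alpha/2` binomial(n, 1/2) quantile and the upper rank
#' its mirror `n - l + 1`, making no distributional assumption.
#'
#' @param values Numeric vector (n >= 1).
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector: `median`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' median_ci(1:100) # CI spans the 40th to the 61st order statistic
median_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) abort("median_ci needs at least one value",
                   class = "nt_invalid_parameter")
  s <- sort(values)
  alpha <- 1 - level
  l <- qbinom(alpha / 2, n, 0.5)
  l <- max(1, l)
  u <- min(n, n - l + 1)
  c(median = stats::median(values), ci_low = s[l], ci_high = s[u])
}

#' Kolmogorov-Smirnov tests
#'
#' One-sample mode (`b = NULL`) tests `a` against a normal distribution with
#' the sample mean and standard deviation (a pragmatic normality screen);
#' two-sample mode compares the empirical distributions of `a` and `b`.
#'
#' @param a,b Numeric samples; `b = NULL` selects the one-sample test.
#' @return Tibble with `test`, `statistic`, `p_value`.
#' @export
ks_tests <- function(a, b = NULL) {
  if (length(a) < 2 || (!is.null(b) && length(b) < 2)) {
    abort("KS tests need at least 2 values per sample",
          class = "nt_invalid_parameter")
  }
  if (is.null(b)) {
    kt <- suppressWarnings(ks.test(a, "pnorm", mean(a), sd(a)))
    tibble(test = "one-sample-normal",
           statistic = unname(kt$statistic), p_value = kt$p.value)
  } else {
    kt <- suppressWarnings(ks.test(a, b))
    tibble(test = "two-sample",
           statistic = unname(kt$statistic), p_value = kt$p.value)
  }
}

#' Cross-modality scale ratio
#'
#' Fold change between two median scales (e.g. STED versus STORM
#' inter-particle distance medians), reported at one decimal as such ratios
#' are customarily quoted.
#'
#' @param numerator_median,denominator_median Medians in the same units.
#' @return Ratio rounded to one decimal.
#' @export
#' @examples
#' scale_ratio(366.5, 42.42) # STED/STORM inter-particle distances (BTX)
scale_ratio <- function(numerator_median, denominator_median) {
  if (!is.finite(denominator_median) || denominator_median == 0) {
    abort("denominator median must be nonzero", class = "nt_invalid_parameter")
  }
  round(numerator_median / denominator_median, 1)
}
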