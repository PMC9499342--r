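# Shared fixtures and independent brute-force oracles.

# uniform disc blob of localizations
blob <- function(cx, cy, n = 20, r = 50) {
  rr <- r * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  tibble::tibble(x = cx + rr * cos(th), y = cy + rr * sin(th))
}

# brute-force Delaunay edge set via the empty-circumcircle property
bf_delaunay_edges <- function(x, y) {
  n <- length(x)
  circum <- function(i, j, k) {
    d <- 2 * (x[i] * (y[j] - y[k]) + x[j] * (y[k] - y[i]) + x[k] * (y[i] - y[j]))
    if (abs(d) < 1e-14) return(NULL)
    a2 <- x[i]^2 + y[i]^2; b2 <- x[j]^2 + y[j]^2; c2 <- x[k]^2 + y[k]^2
    ox <- (a2 * (y[j] - y[k]) + b2 * (y[k] - y[i]) + c2 * (y[i] - y[j])) / d
    oy <- (a2 * (x[k] - x[j]) + b2 * (x[i] - x[k]) + c2 * (x[j] - x[i])) / d
    c(ox, oy, sqrt((x[i] - ox)^2 + (y[i] - oy)^2))
  }
  edges <- matrix(integer(), 0, 2)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    cc <- circum(i, j, k)
    if (is.null(cc)) next
    d <- sqrt((x - cc[1])^2 + (y - cc[2])^2)
    if (all(d[-c(i, j, k)] > cc[3] - 1e-12)) {
      edges <- rbind(edges, c(i, j), c(j, k), c(i, k))
    }
  }
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

# sorted unique edge matrix from an nt_delaunay-style edge tibble
canon_edges <- function(i, j) {
  e <- cbind(pmin(i, j), pmax(i, j))
  unique(e[order(e[, 1], e[, 2]), , drop = FALSE])
}

# brute-force nearest-neighbour distances via the full distance matrix
bf_nn_dist <- function(x, y) {
  D <- as.matrix(dist(cbind(x, y)))
  diag(D) <- Inf
  apply(D, 1, min)
}

# brute-force G function on a grid
bf_g_function <- function(x, y, d_grid) {
  dmin <- bf_nn_dist(x, y)
  vapply(d_grid, function(d) mean(dmin < d), numeric(1))
}

# a localization tibble with a region attribute
with_region <- function(df, region) {
  attr(df, "region") <- region
  df
}

# fast config for unit tests (fewer reference/envelope simulations)
test_config <- function(...) {
  pipeline_config(noise_simulations = 20, csr_simulations = 19, ...)
}
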