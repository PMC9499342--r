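# Per-cluster and per-ROI metrics: concave-boundary areas, densities, the
# farthest-pair ellipse fit, centroid distances and peripheral/central
# region comparisons.

#' Concave boundary area of a point cluster
#'
#' Area of the boundary polygon of a point set at a given shrink factor,
#' analogous to the MATLAB-style `boundary` function: `shrink = 0` gives the
#' convex hull, `shrink = 1` the tightest single boundary that still encloses
#' every point. Intermediate values interpolate along the ladder of critical
#' alpha values of the Delaunay triangulation.
#'
#' @param points Data frame with `x`, `y` (nm); at least 3 non-collinear.
#' @param shrink Shrink factor in \[0, 1\] (default 0.5).
#' @return Area in nm^2.
#' @export
cluster_area <- function(points, shrink = 0.5) {
  stopifnot(shrink >= 0, shrink <= 1)
  xy <- as_xy(points)
  if (length(xy$x) < 3) abort("area undefined for fewer than 3 points",
                              class = "nt_degenerate")
  dt <- tryCatch(nt_delaunay(xy$x, xy$y),
                 error = function(e) abort("area undefined for degenerate (collinear) points",
                                           class = "nt_degenerate"))
  # smallest alpha that keeps every point on the shape
  vert_min <- rep(Inf, length(xy$x))
  for (c in 1:3) {
    v <- dt$triangles[, c]
    agg <- tapply(dt$circumradius, v, min)
    idx <- as.integer(names(agg))
    vert_min[idx] <- pmin(vert_min[idx], as.numeric(agg))
  }
  a_crit <- max(vert_min)
  ladder <- sort(unique(dt$circumradius[dt$circumradius >= a_crit]))
  alpha <- if (length(ladder) == 1) ladder else {
    ladder[1 + round((1 - shrink) * (length(ladder) - 1))]
  }
  keep <- dt$circumradius <= alpha
  sum(triangle_area(xy$x, xy$y, dt$triangles[keep, , drop = FALSE]))
}

#' Farthest-pair ellipse fit of a cluster
#'
#' Geometric ellipse fit driven by the cluster's extreme points: the farthest
#' point pair defines the major axis (length 2a); the cluster is translated
#' so one endpoint sits at the origin and rotated until the pair is
#' horizontal; the minor axis 2b is then the vertical span of the rotated
#' points. Eccentricity is `sqrt(1 - (b/a)^2)`. Unlike a direct
#' least-squares conic fit, the axes can never exceed the cluster dimensions.
#'
#' @param points Data frame with `x`, `y` (nm); at least 3 points.
#' @return An `nt_ellipse` list: `a`, `b` (semi-axes, nm), `eccentricity`,
#'   `orientation` (radians of the major axis), `center` (midpoint of the
#'   farthest pair).
#' @export
ellipse_fit <- function(points) {
  xy <- as_xy(points)
  n <- length(xy$x)
  if (n < 3) abort("ellipse fit needs at least 3 points", class = "nt_degenerate")
  d2 <- as.matrix(dist(cbind(xy$x, xy$y)))
  w <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  i <- w[1]; j <- w[2]
  if (d2[i, j] == 0) abort("all points identical", class = "nt_degenerate")
  a <- d2[i, j] / 2
  ang <- atan2(xy$y[j] - xy$y[i], xy$x[j] - xy$x[i])
  xr <- (xy$x - xy$x[i]) * cos(-ang) - (xy$y - xy$y[i]) * sin(-ang)
  yr <- (xy$x - xy$x[i]) * sin(-ang) + (xy$y - xy$y[i]) * cos(-ang)
  b <- (max(yr) - min(yr)) / 2
  ecc <- sqrt(max(0, 1 - (b / a)^2))
  structure(list(a = a, b = b, eccentricity = ecc,
                 orientation = ang %% pi,
                 center = c(x = mean(xy$x[c(i, j)]), y = mean(xy$y[c(i, j)]))),
            class = "nt_ellipse")
}

#' @export
print.nt_ellipse <- function(x, ...) {
  cat(sprintf("<ellipse: a = %.2f, b = %.2f nm, e = %.3f, theta = %.2f rad>\n",
              x$a, x$b, x$eccentricity, x$orientation))
  invisible(x)
}

#' Direct least-squares ellipse fit (cross-check only)
#'
#' Classical direct conic least-squares ellipse fit. Retained as an optional
#' cross-check: on small clusters it can return axis lengths that greatly
#' exceed the cluster dimensions, which is why [ellipse_fit()] is the default
#' shape estimator.
#'
#' @param points Data frame with `x`, `y`.
#' @return An `nt_ellipse` (orientation of the major axis, semi-axes, e).
#' @export
ellipse_fit_lsq <- function(points) {
  xy <- as_xy(points)
  if (length(xy$x) < 5) abort("direct ellipse fit needs at least 5 points",
                              class = "nt_degenerate")
  x <- xy$x - mean(xy$x); y <- xy$y - mean(xy$y)
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)),
                 error = function(e) -qr.solve(S3 + diag(1e-10, 3), t(S2)))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  pick <- which(cond > 1e-12)
  if (length(pick) == 0) pick <- which.max(cond)
  a1 <- V[, pick[1]]
  coef <- c(a1, Tm %*% a1)   # general conic A x^2 + B xy + C y^2 + D x + E y + F
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; Fc <- coef[6]
  disc <- B^2 - 4 * A * C # < 0 for an ellipse
  if (disc >= 0) abort("direct fit did not produce an ellipse",
                       class = "nt_degenerate")
  q <- 2 * (A * E^2 + C * D^2 - B * D * E + disc * Fc)
  s <- sqrt((A - C)^2 + B^2)
  ax1 <- -sqrt(q * (A + C + s)) / disc
  ax2 <- -sqrt(q * (A + C - s)) / disc
  a <- max(ax1, ax2); b <- min(ax1, ax2)
  theta <- 0.5 * atan2(-B, C - A)
  if (ax1 < ax2) theta <- theta + pi / 2
  structure(list(a = a, b = b, eccentricity = sqrt(max(0, 1 - (b / a)^2)),
                 orientation = theta %% pi,
                 center = c(x = mean(xy$x), y = mean(xy$y))),
            class = "nt_ellipse")
}

#' Inter-cluster centroid distances
#'
#' Distances between nanocluster centroids restricted to Delaunay-adjacent
#' pairs, discarding the biologically irrelevant long-range connections an
#' all-pairs listing would include. With exactly two clusters the single pair
#' distance is returned.
#'
#' @param clustering An `nt_clustering`, or a data frame with `x`, `y`,
#'   `cluster` columns.
#' @return Numeric vector of edge lengths in nm (empty when < 2 clusters).
#' @export
inter_centroid_distances <- function(clustering) {
  cen <- cluster_centroids(clustering)
  centroid_edge_lengths(cen$cx, cen$cy)
}

centroid_edge_lengths <- function(cx, cy) {
  if (length(cx) < 2) return(numeric(0))
  if (length(cx) == 2) return(sqrt(diff(cx)^2 + diff(cy)^2))
  dt <- tryCatch(nt_delaunay(cx, cy), error = function(e) NULL)
  if (is.null(dt)) {
    # collinear centroids: consecutive gaps along the line
    o <- order(cx, cy)
    return(sqrt(diff(cx[o])^2 + diff(cy[o])^2))
  }
  dt$edges$length
}

cluster_centroids <- function(clustering) {
  stopifnot(all(c("x", "y", "cluster") %in% names(clustering)))
  as_tibble(clustering) |>
    dplyr::filter(.data$cluster > 0) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(cx = mean(.data$x), cy = mean(.data$y),
                     n = dplyr::n(), .groups = "drop")
}

#' Tag localizations as peripheral or central within a cell outline
#'
#' Normalized depth is the distance to the cell boundary divided by the
#' maximum depth over all points. Points with depth at most
#' `peripheral_fraction` are peripheral, points with depth at least 0.5 are
#' central; the band in between stays untagged, mirroring disjoint ROI
#' selection. Points outside the polygon are tagged `"outside"`.
#'
#' @param locs Data frame with `x`, `y` (nm).
#' @param boundary Data frame with `x`, `y` vertices of a closed cell
#'   outline polygon (first vertex needs not be repeated).
#' @param peripheral_fraction Depth cut for the peripheral tag (default 0.3).
#' @return Character vector of tags: `"peripheral"`, `"central"`,
#'   `"intermediate"` or `"outside"`.
#' @export
partition_regions <- function(locs, boundary, peripheral_fraction = 0.3) {
  xy <- as_xy(locs)
  bx <- boundary$x; by <- boundary$y
  if (length(bx) < 3) abort("boundary polygon needs at least 3 vertices",
                            class = "nt_invalid_parameter")
  inside <- point_in_polygon(xy$x, xy$y, bx, by)
  depth <- boundary_distance(xy$x, xy$y, bx, by)
  maxd <- max(depth[inside], 0)
  nd <- if (maxd > 0) depth / maxd else rep(0, length(depth))
  tag <- rep("intermediate", length(xy$x))
  tag[nd <= peripheral_fraction] <- "peripheral"
  tag[nd >= 0.5] <- "central"
  tag[!inside] <- "outside"
  if (any(!inside)) {
    inform(sprintf("%d localization(s) outside the boundary polygon",
                   sum(!inside)))
  }
  tag
}

# even-odd ray crossing test, vectorized over points
point_in_polygon <- function(px, py, bx, by) {
  n <- length(bx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((by[i] > py) != (by[j] > py)) &
      (px < (bx[j] - bx[i]) * (py - by[i]) / (by[j] - by[i]) + bx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# min distance of each point to the polygon boundary segments
boundary_distance <- function(px, py, bx, by) {
  n <- length(bx)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ex <- bx[i] - bx[j]; ey <- by[i] - by[j]
    len2 <- ex^2 + ey^2
    t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - bx[j]) * ex + (py - by[j]) * ey) / len2))
    dx <- px - (bx[j] + t * ex); dy <- py - (by[j] + t * ey)
    d2 <- pmin(d2, dx^2 + dy^2)
    j <- i
  }
  sqrt(d2)
}

#' Summarize nanocluster metrics per region
#'
#' Computes per-cluster metrics (size, concave-boundary area, intra-cluster
#' molecule density, ellipse shape) and region-level summaries (percent
#' clustered localizations, inter-centroid distances), reporting the median
#' with a distribution-free 95% confidence interval for every metric.
#' Clusters are assigned to the majority region of their members.
#'
#' @param clustering An `nt_clustering` (or data frame with `x`, `y`,
#'   `cluster`).
#' @param regions Optional character vector of region tags per localization
#'   (see [partition_regions()]); `NULL` summarizes the whole ROI.
#' @param shrink Boundary shrink factor for [cluster_area()].
#' @return An `nt_metrics` object: list with `clusters` (per-cluster tibble:
#'   `cluster`, `region`, `n`, `area_nm2`, `density_per_um2`, `cx`, `cy`,
#'   `eccentricity`, `major_axis_nm`) and `summary` (tidy tibble: `metric`,
#'   `region`, `n`, `median`, `ci_low`, `ci_high`). Areas are nm^2,
#'   densities molecules/um^2, distances nm.
#' @export
summarize_clusters <- function(clustering, regions = NULL, shrink = 0.5) {
  df <- as_tibble(clustering)
  stopifnot(all(c("x", "y", "cluster") %in% names(df)))
  n_all <- nrow(df)
  regions <- regions %||% rep("whole", n_all)
  stopifnot(length(regions) == n_all)
  df$region <- regions

  per_cluster <- df |>
    dplyr::filter(.data$cluster > 0) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_map(function(g, key) {
      area <- tryCatch(cluster_area(g, shrink), error = function(e) NA_real_)
      ell <- tryCatch(ellipse_fit(g), error = function(e) NULL)
      tibble(cluster = key$cluster,
             region = names(which.max(table(g$region))),
             n = nrow(g),
             area_nm2 = area,
             density_per_um2 = if (is.na(area) || area == 0) NA_real_ else nrow(g) / area * 1e6,
             cx = mean(g$x), cy = mean(g$y),
             eccentricity = if (is.null(ell)) NA_real_ else ell$eccentricity,
             major_axis_nm = if (is.null(ell)) NA_real_ else 2 * ell$a)
    }) |>
    dplyr::bind_rows()

  summ <- purrr::map(unique(regions[regions != "outside"]), function(reg) {
    in_reg <- df$region == reg
    cl <- per_cluster[per_cluster$region == reg, , drop = FALSE]
    rows <- list(
      metric_row("pct_localizations_in_nanoclusters", reg,
                 100 * sum(df$cluster[in_reg] > 0) / max(1, sum(in_reg))),
      summary_row("nanocluster_area", reg, cl$area_nm2),
      summary_row("molecule_density", reg, cl$density_per_um2),
      summary_row("localizations_per_nanocluster", reg, as.numeric(cl$n)),
      summary_row("inter_centroid_distance", reg,
                  centroid_edge_lengths(cl$cx, cl$cy)),
      summary_row("eccentricity", reg, cl$eccentricity),
      summary_row("major_axis_length", reg, cl$major_axis_nm)
    )
    dplyr::bind_rows(rows)
  }) |> dplyr::bind_rows()

  structure(list(clusters = per_cluster, summary = summ),
            class = "nt_metrics")
}

metric_row <- function(metric, region, value) {
  tibble(metric = metric, region = region, n = 1L,
         median = value, ci_low = NA_real_, ci_high = NA_real_)
}

summary_row <- function(metric, region, values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) {
    return(tibble(metric = metric, region = region, n = 0L,
                  median = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  }
  ci <- median_ci(values)
  tibble(metric = metric, region = region, n = length(values),
         median = ci[["median"]], ci_low = ci[["ci_low"]],
         ci_high = ci[["ci_high"]])
}

#' @export
print.nt_metrics <- function(x, ...) {
  cat(sprintf("<nanocluster metrics: %d clusters>\n", nrow(x$clusters)))
  print(x$summary, n = Inf)
  invisible(x)
}

#' @rdname summarize_clusters
#' @param x An `nt_metrics` object.
#' @param ... Unused.
#' @export
tidy.nt_metrics <- function(x, ...) x$summary
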