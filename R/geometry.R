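# Low-level planar geometry shared by the clustering, alpha-shape and
# spatial-statistics modules. All coordinates are in nanometres.

#' Axis-aligned rectangular region
#'
#' Regions define the spatial support for synthetic fields and for the
#' complete-spatial-randomness (CSR) null patterns used throughout the
#' package.
#'
#' @param width,height Extent in nm.
#' @param xmin,ymin Lower-left corner in nm.
#' @return A `nt_region` object.
#' @export
#' @examples
#' region_rect(10000, 10000) # a 10 x 10 um ROI
region_rect <- function(width, height, xmin = 0, ymin = 0) {
  if (!is.finite(width) || !is.finite(height) || width <= 0 || height <= 0) {
    abort("region width and height must be positive", class = "nt_invalid_parameter")
  }
  structure(
    list(shape = "rect", xmin = xmin, ymin = ymin,
         xmax = xmin + width, ymax = ymin + height),
    class = "nt_region"
  )
}

#' Disc-shaped region
#'
#' @param cx,cy Centre in nm.
#' @param radius Radius in nm.
#' @return A `nt_region` object.
#' @export
region_disc <- function(cx, cy, radius) {
  if (!is.finite(radius) || radius <= 0) {
    abort("disc radius must be positive", class = "nt_invalid_parameter")
  }
  structure(list(shape = "disc", cx = cx, cy = cy, r = radius),
            class = "nt_region")
}

#' @export
print.nt_region <- function(x, ...) {
  if (x$shape == "rect") {
    cat(sprintf("<region: rectangle [%g, %g] x [%g, %g] nm>\n",
                x$xmin, x$xmax, x$ymin, x$ymax))
  } else {
    cat(sprintf("<region: disc centre (%g, %g), radius %g nm>\n", x$cx, x$cy, x$r))
  }
  invisible(x)
}

region_area <- function(region) {
  if (region$shape == "rect") {
    (region$xmax - region$xmin) * (region$ymax - region$ymin)
  } else {
    pi * region$r^2
  }
}

region_sample <- function(region, n) {
  if (n == 0) return(tibble(x = numeric(), y = numeric()))
  if (region$shape == "rect") {
    tibble(x = runif(n, region$xmin, region$xmax),
           y = runif(n, region$ymin, region$ymax))
  } else {
    # uniform in disc via sqrt radius
    r <- region$r * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    tibble(x = region$cx + r * cos(th), y = region$cy + r * sin(th))
  }
}

region_contains <- function(region, x, y) {
  if (region$shape == "rect") {
    x >= region$xmin & x <= region$xmax & y >= region$ymin & y <= region$ymax
  } else {
    (x - region$cx)^2 + (y - region$cy)^2 <= region$r^2
  }
}

# Delaunay triangulation wrapper. Returns a list with the triangle index
# matrix (rows = triangles, 1-based vertex indices), the unique edge table
# and per-triangle circumradii.
nt_delaunay <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) {
    abort("Delaunay triangulation needs at least 3 points",
          class = "nt_degenerate")
  }
  if (anyDuplicated(cbind(x, y))) {
    abort("Delaunay triangulation undefined for duplicated points",
          class = "nt_degenerate")
  }
  tri <- tryCatch(
    .delaunay_cpp(as.numeric(x), as.numeric(y)),
    error = function(e) abort(paste0("degenerate point configuration: ",
                                     conditionMessage(e)),
                              class = "nt_degenerate")
  )
  # unique undirected edges
  e <- rbind(tri[, c(1, 2), drop = FALSE],
             tri[, c(2, 3), drop = FALSE],
             tri[, c(3, 1), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  len <- sqrt((x[e[, 1]] - x[e[, 2]])^2 + (y[e[, 1]] - y[e[, 2]])^2)
  list(
    triangles = tri,
    edges = tibble(i = e[, 1], j = e[, 2], length = len),
    circumradius = triangle_circumradius(x, y, tri)
  )
}

triangle_circumradius <- function(x, y, tri) {
  ax <- x[tri[, 1]]; ay <- y[tri[, 1]]
  bx <- x[tri[, 2]]; by <- y[tri[, 2]]
  cx <- x[tri[, 3]]; cy <- y[tri[, 3]]
  a <- sqrt((bx - cx)^2 + (by - cy)^2)
  b <- sqrt((ax - cx)^2 + (ay - cy)^2)
  cc <- sqrt((ax - bx)^2 + (ay - by)^2)
  area2 <- abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay)) # 2*area
  r <- a * b * cc / (2 * pmax(area2, .Machine$double.xmin))
  r[area2 == 0] <- Inf
  r
}

triangle_area <- function(x, y, tri) {
  ax <- x[tri[, 1]]; ay <- y[tri[, 1]]
  bx <- x[tri[, 2]]; by <- y[tri[, 2]]
  cx <- x[tri[, 3]]; cy <- y[tri[, 3]]
  abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay)) / 2
}

# k-nearest-neighbour indices and distances (self excluded)
nt_knn <- function(x, y, k) {
  n <- length(x)
  if (k < 1) abort("k must be >= 1", class = "nt_invalid_parameter")
  if (n < k + 1) {
    abort(sprintf("need at least %d points for k = %d", k + 1, k),
          class = "nt_invalid_parameter")
  }
  .knn_cpp(as.numeric(x), as.numeric(y), as.integer(k))
}

# nearest-neighbour distance of every point to any other point
nt_nn_dist <- function(x, y) {
  if (length(x) < 2) abort("need at least 2 points", class = "nt_invalid_parameter")
  .nn_dist_cpp(as.numeric(x), as.numeric(y))
}
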