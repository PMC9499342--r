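# Alpha-shape based inter-cluster similarity and iterative merging.
#
# For a pair of clusters, the alpha-complex of their union is taken at the
# smallest alpha whose shape encloses every point of one of the clusters
# (the smaller one). Similarity counts triangulation edges joining the two
# clusters inside that complex, normalized by the smaller cluster size; the
# alpha selection makes well-separated clusters come out with similarity
# exactly zero, so they are never merged.

#' Minimal enclosing alpha-shape
#'
#' Computes the alpha-complex of `points` at the smallest alpha on the
#' Delaunay critical-value ladder such that every target point lies in or on
#' the shape (i.e. is a vertex of at least one retained triangle). As alpha
#' grows to the largest circumradius the shape becomes the convex hull.
#'
#' @param points Data frame with `x`, `y` (nm): the union point set.
#' @param target Indices (or logical mask) of the points that must be
#'   enclosed; defaults to all points.
#' @return An `nt_alpha_shape`: list with `alpha`, the retained `triangles`,
#'   the complex `edges` tibble, `area` (nm^2) and the input points.
#' @export
minimal_enclosing_alpha <- function(points, target = NULL) {
  xy <- as_xy(points)
  n <- length(xy$x)
  if (is.null(target)) target <- seq_len(n)
  if (is.logical(target)) target <- which(target)
  stopifnot(length(target) >= 1, all(target >= 1 & target <= n))
  dt <- tryCatch(nt_delaunay(xy$x, xy$y), error = function(e) e)
  if (inherits(dt, "error")) {
    return(collinear_alpha_shape(xy, target))
  }
  # minimum circumradius over triangles incident to each vertex
  vert_min <- rep(Inf, n)
  for (c in 1:3) {
    v <- dt$triangles[, c]
    agg <- tapply(dt$circumradius, v, min)
    idx <- as.integer(names(agg))
    vert_min[idx] <- pmin(vert_min[idx], as.numeric(agg))
  }
  alpha <- max(vert_min[target])
  keep <- dt$circumradius <= alpha
  tri <- dt$triangles[keep, , drop = FALSE]
  edges <- complex_edges(tri, xy)
  structure(list(alpha = alpha, triangles = tri, edges = edges,
                 area = sum(triangle_area(xy$x, xy$y, tri)),
                 x = xy$x, y = xy$y, degenerate = FALSE),
            class = "nt_alpha_shape")
}

complex_edges <- function(tri, xy) {
  if (nrow(tri) == 0) return(tibble(i = integer(), j = integer(),
                                    length = numeric()))
  e <- rbind(tri[, c(1, 2), drop = FALSE], tri[, c(2, 3), drop = FALSE],
             tri[, c(3, 1), drop = FALSE])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  tibble(i = e[, 1], j = e[, 2],
         length = sqrt((xy$x[e[, 1]] - xy$x[e[, 2]])^2 +
                       (xy$y[e[, 1]] - xy$y[e[, 2]])^2))
}

# Degenerate (collinear or < 3 point) input: fall back to a segment chain
# along the principal direction, with alpha = the largest gap the target
# points span.
collinear_alpha_shape <- function(xy, target) {
  inform("degenerate point set: falling back to segment-buffer alpha shape")
  n <- length(xy$x)
  t <- order(xy$x + xy$y * 1e-9, xy$y)
  gaps <- sqrt(diff(xy$x[t])^2 + diff(xy$y[t])^2)
  pos <- match(seq_len(n), t)
  # alpha must bridge every gap adjacent to a target point
  need <- unique(c(pos[target], pmax(pos[target] - 1, 1)))
  need <- need[need < n]
  alpha <- if (length(need) == 0) 0 else max(gaps[need]) / 2
  keep <- which(gaps <= 2 * alpha)
  edges <- tibble(i = t[keep], j = t[keep + 1], length = gaps[keep])
  structure(list(alpha = alpha, triangles = matrix(integer(), 0, 3),
                 edges = edges, area = 0, x = xy$x, y = xy$y,
                 degenerate = TRUE),
            class = "nt_alpha_shape")
}

#' @export
print.nt_alpha_shape <- function(x, ...) {
  cat(sprintf("<alpha shape: alpha = %.3f nm, %d triangles, area %.1f nm^2>\n",
              x$alpha, nrow(x$triangles), x$area))
  invisible(x)
}

#' Alpha-shape triangles as WKT (for external inspection)
#'
#' @param shape An `nt_alpha_shape`.
#' @return A `MULTIPOLYGON` WKT string of the retained triangles.
#' @export
alpha_shape_wkt <- function(shape) {
  if (nrow(shape$triangles) == 0) return("MULTIPOLYGON EMPTY")
  polys <- apply(shape$triangles, 1, function(v) {
    v <- c(v, v[1])
    sprintf("((%s))", paste(sprintf("%.6g %.6g", shape$x[v], shape$y[v]),
                            collapse = ", "))
  })
  paste0("MULTIPOLYGON (", paste(polys, collapse = ", "), ")")
}

#' Alpha-shape similarity of two clusters
#'
#' Builds the minimal enclosing alpha-complex of the union (target = the
#' smaller cluster) and returns the number of complex edges joining the two
#' clusters, divided by the smaller cluster size. Zero when no such edge
#' exists — by construction the typical outcome for well-separated clusters.
#' Symmetric in its arguments.
#'
#' @param a,b Data frames with `x`, `y` (nm); both non-empty.
#' @return Non-negative similarity.
#' @export
pair_similarity <- function(a, b) {
  xa <- as_xy(a); xb <- as_xy(b)
  na <- length(xa$x); nb <- length(xb$x)
  stopifnot(na >= 1, nb >= 1)
  if (na + nb < 3) return(0)
  pts <- tibble(x = c(xa$x, xb$x), y = c(xa$y, xb$y))
  target <- if (na <= nb) seq_len(na) else na + seq_len(nb)
  shape <- minimal_enclosing_alpha(pts, target)
  in_a <- c(rep(TRUE, na), rep(FALSE, nb))
  cross <- xor(in_a[shape$edges$i], in_a[shape$edges$j])
  sum(cross) / min(na, nb)
}

#' Merge clusters by iterated maximum alpha-shape similarity
#'
#' Starting from a (typically fine) labelling, repeatedly merges the single
#' pair of clusters with the globally maximal nonzero similarity, recomputing
#' similarities involving the merged cluster, until every remaining pair has
#' similarity zero; clusters below `min_cluster_size` are then discarded
#' (members relabelled noise). With the second level of the community
#' hierarchy as input this reproduces the combined graph + alpha-shape
#' analysis, which yields tighter, more circular nanoclusters than the
#' coarse graph clustering alone.
#'
#' @param locs Data frame with `x`, `y` (nm).
#' @param labels Integer labels per row (0 = noise; never merged).
#' @param min_cluster_size Final size filter.
#' @return Integer label vector, contiguous, 0 = noise.
#' @export
merge_by_similarity <- function(locs, labels, min_cluster_size = 15) {
  xy <- as_xy(locs)
  stopifnot(length(labels) == length(xy$x))
  labels <- relabel_contiguous(labels)
  ids <- setdiff(sort(unique(labels)), 0L)
  if (length(ids) >= 2) {
    pts_of <- function(k) tibble(x = xy$x[labels == k], y = xy$y[labels == k])
    sim <- matrix(0, length(ids), length(ids))
    for (i in seq_along(ids)) {
      for (j in seq_len(i - 1)) {
        sim[i, j] <- sim[j, i] <- pair_similarity(pts_of(ids[i]), pts_of(ids[j]))
      }
    }
    alive <- rep(TRUE, length(ids))
    repeat {
      sub <- sim
      sub[!alive, ] <- 0; sub[, !alive] <- 0
      m <- max(sub)
      if (m <= 0) break
      w <- which(sub == m, arr.ind = TRUE)[1, ]
      i <- min(w); j <- max(w)
      labels[labels == ids[j]] <- ids[i]
      alive[j] <- FALSE
      # lazy invalidation: refresh only pairs involving the merged cluster
      for (k in which(alive)) {
        if (k == i) next
        sim[i, k] <- sim[k, i] <- pair_similarity(pts_of(ids[i]), pts_of(ids[k]))
      }
    }
  }
  filter_min_size(labels, min_cluster_size)
}

#' Combined graph + alpha-shape nanocluster detection
#'
#' Applies [merge_by_similarity()] to the second level (counted from the
#' coarsest) of the community hierarchy produced by
#' [cluster_localizations()], mirroring the combined analysis in which the
#' alpha-shape similarity re-merges an intentionally over-split labelling.
#'
#' @param clustering An `nt_clustering` from [cluster_localizations()].
#' @param level Hierarchy level to merge (default 2; clipped to available
#'   levels).
#' @return A new `nt_clustering` with the merged labels in `cluster`.
#' @export
merge_nanoclusters <- function(clustering, level = 2) {
  stopifnot(inherits(clustering, "nt_clustering"))
  hier <- attr(clustering, "hierarchy")
  config <- attr(clustering, "config")
  if (length(hier) == 0) return(clustering)
  labels <- hier[[min(level, length(hier))]]
  merged <- merge_by_similarity(clustering, labels,
                                min_cluster_size = config$min_cluster_size)
  out <- dplyr::mutate(as_tibble(clustering), cluster = merged)
  structure(out, region = attr(clustering, "region"), hierarchy = hier,
            r_o = attr(clustering, "r_o"), config = config,
            class = c("nt_clustering", class(out)))
}
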