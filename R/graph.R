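# Graph-based nanocluster detection: adaptive length scale, weighted kNN
# graph, CSR-calibrated noise removal, multi-level community detection,
# robustness-gated merging and a minimum-size filter.

#' ROI-specific length scale from kNN distances
#'
#' `r_o` is the median over all localizations of the distance to the K-th
#' nearest neighbour. It adapts the graph weights to the local density of the
#' ROI, so identical settings can be applied across heterogeneous samples.
#'
#' @param locs Data frame with `x`, `y` in nm (or a two-column matrix).
#' @param K Neighbour count.
#' @return Length scale in nm.
#' @export
estimate_length_scale <- function(locs, K) {
  xy <- as_xy(locs)
  if (K < 1) abort("K must be >= 1", class = "nt_invalid_parameter")
  if (length(xy$x) < K + 1) {
    abort(sprintf("need at least %d points for K = %d", K + 1, K),
          class = "nt_invalid_parameter")
  }
  stats::median(.kth_nn_dist_cpp(as.numeric(xy$x), as.numeric(xy$y),
                                 as.integer(K)))
}

as_xy <- function(locs) {
  if (is.matrix(locs)) {
    list(x = locs[, 1], y = locs[, 2])
  } else {
    stopifnot(all(c("x", "y") %in% names(locs)))
    list(x = locs$x, y = locs$y)
  }
}

#' Build the weighted kNN cluster graph
#'
#' An undirected edge joins i and j when either is among the other's K
#' nearest neighbours (symmetric kNN rule); the weight is the Gaussian kernel
#' `w_ij = exp(-d_ij^2 / r_o^2)`, so w = 1 for coincident points and decays
#' on the ROI length scale.
#'
#' @param locs Data frame with `x`, `y` (nm).
#' @param K Neighbour count.
#' @param r_o Length scale in nm (defaults to [estimate_length_scale()]).
#' @return An `nt_cluster_graph`: list with the `igraph` object, `r_o`, `K`
#'   and the coordinates.
#' @export
build_knn_graph <- function(locs, K, r_o = NULL) {
  xy <- as_xy(locs)
  n <- length(xy$x)
  r_o <- r_o %||% estimate_length_scale(locs, K)
  if (!is.finite(r_o) || r_o <= 0) abort("r_o must be positive",
                                         class = "nt_invalid_parameter")
  el <- .knn_edges_cpp(as.numeric(xy$x), as.numeric(xy$y),
                       as.integer(min(K, n - 1)))
  a <- el$i; b <- el$j; d <- el$dist
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- exp(-(d / r_o)^2)
  igraph::E(g)$dist <- d
  structure(list(graph = g, r_o = r_o, K = K, x = xy$x, y = xy$y),
            class = "nt_cluster_graph")
}

#' @export
print.nt_cluster_graph <- function(x, ...) {
  cat(sprintf("<cluster graph: %d nodes, %d edges, K = %d, r_o = %.2f nm>\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$K, x$r_o))
  invisible(x)
}

#' Export the cluster graph as an edge list
#'
#' @param cg An `nt_cluster_graph`.
#' @return Tibble with columns `i`, `j`, `dist`, `weight`.
#' @export
graph_edges <- function(cg) {
  el <- igraph::as_edgelist(cg$graph)
  tibble(i = el[, 1], j = el[, 2],
         dist = igraph::E(cg$graph)$dist,
         weight = igraph::E(cg$graph)$weight)
}

#' Classify localizations as clustered or noise against a CSR null
#'
#' Each node is scored by the sum of its incident edge weights; the decision
#' threshold is the `1 - alpha_sig` quantile of node scores pooled over CSR
#' reference graphs built with the same n, region, K and `r_o`. `alpha_sig`
#' is therefore the maximum probability that a completely randomly
#' distributed localization is classified as clustered.
#'
#' @param cg An `nt_cluster_graph`.
#' @param alpha_sig Significance level (default 0.05).
#' @param region Region of the ROI (for CSR simulation).
#' @param n_simulations Number of CSR reference graphs (>= 20 recommended).
#' @param seed Integer seed for the reference simulations.
#' @return Logical vector: `TRUE` = clustered candidate.
#' @export
classify_noise <- function(cg, alpha_sig = 0.05, region, n_simulations = 20,
                           seed = NULL) {
  stopifnot(inherits(cg, "nt_cluster_graph"))
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(cg$graph)
  scores <- igraph::strength(cg$graph)
  k_ref <- as.integer(min(cg$K, n - 1))
  ref <- purrr::map(seq_len(n_simulations), function(s) {
    p <- region_sample(region, n)
    as.numeric(.knn_scores_cpp(p$x, p$y, k_ref, cg$r_o))
  })
  thr <- stats::quantile(unlist(ref), probs = 1 - alpha_sig, names = FALSE,
                         type = 8)
  scores > thr
}

#' Multi-level community detection on the cluster graph
#'
#' Runs weighted modularity-based multi-level (Louvain) community detection
#' and returns every level of the hierarchy, ordered coarse to fine. With a
#' fixed seed and the canonical node ordering used by the pipeline the result
#' is deterministic.
#'
#' @param cg An `nt_cluster_graph`.
#' @param seed Integer seed.
#' @return List of integer membership vectors, coarsest first.
#' @export
detect_communities <- function(cg, seed = NULL) {
  stopifnot(inherits(cg, "nt_cluster_graph"))
  if (igraph::vcount(cg$graph) == 0) return(list(integer(0)))
  if (!is.null(seed)) set.seed(seed)
  cl <- igraph::cluster_louvain(cg$graph)
  mem <- cl$memberships
  if (is.null(mem)) mem <- matrix(igraph::membership(cl), nrow = 1)
  # igraph stores levels finest-first; return coarsest-first
  lapply(rev(seq_len(nrow(mem))), function(r) relabel_contiguous(mem[r, ]))
}

relabel_contiguous <- function(labels) {
  pos <- labels > 0
  u <- unique(labels[pos])
  out <- integer(length(labels))
  out[pos] <- match(labels[pos], u)
  out
}

#' Merge communities that are robustly interconnected
#'
#' Two communities are merged only when the subgraph induced by their union
#' stays connected across the two groups after deletion of any single node,
#' i.e. at least two node-disjoint paths join them (no articulation node
#' separates the pair). Applied repeatedly until a fixpoint.
#'
#' @param labels Integer membership vector (0 allowed = noise, not merged).
#' @param cg The `nt_cluster_graph` the labels live on.
#' @return Relabelled integer vector.
#' @export
robust_merge <- function(labels, cg) {
  stopifnot(inherits(cg, "nt_cluster_graph"))
  g <- cg$graph
  labels <- relabel_contiguous(labels)
  repeat {
    merged <- FALSE
    ids <- setdiff(sort(unique(labels)), 0L)
    if (length(ids) < 2) break
    el <- igraph::as_edgelist(g, names = FALSE)
    la <- labels[el[, 1]]; lb <- labels[el[, 2]]
    cross <- la != lb & la > 0 & lb > 0
    pairs <- unique(cbind(pmin(la[cross], lb[cross]),
                          pmax(la[cross], lb[cross])))
    if (nrow(pairs) == 0) break
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      if (robustly_connected(g, which(labels == a), which(labels == b))) {
        labels[labels == b] <- a
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  relabel_contiguous(labels)
}

# TRUE when A-nodes and B-nodes stay mutually reachable in the union
# subgraph after removal of any single node
robustly_connected <- function(g, va, vb) {
  nodes <- c(va, vb)
  sub <- igraph::induced_subgraph(g, nodes)
  ia <- seq_along(va)
  ib <- seq_along(vb) + length(va)
  if (!pair_reachable(sub, ia, ib)) return(FALSE)
  arts <- as.integer(igraph::articulation_points(sub))
  for (v in arts) {
    s2 <- igraph::delete_vertices(sub, v)
    ia2 <- shift_idx(ia, v); ib2 <- shift_idx(ib, v)
    if (length(ia2) == 0 || length(ib2) == 0) return(FALSE)
    if (!pair_reachable(s2, ia2, ib2)) return(FALSE)
  }
  TRUE
}

shift_idx <- function(idx, removed) {
  idx <- idx[idx != removed]
  idx - (idx > removed)
}

pair_reachable <- function(g, ia, ib) {
  comp <- igraph::components(g)$membership
  length(intersect(comp[ia], comp[ib])) > 0
}

#' Detect nanoclusters in a localization table
#'
#' Full graph-clustering pipeline: estimate the ROI length scale, build the
#' weighted kNN graph, remove CSR-consistent noise, rebuild the graph on the
#' survivors with a fresh length scale, find the multi-level community
#' hierarchy, merge robustly interconnected communities, and discard clusters
#' below the minimum size (their members are relabelled noise).
#'
#' @param locs Localization tibble with `x`, `y` (nm).
#' @param config A [pipeline_config()].
#' @param region ROI region; defaults to the attribute attached by the
#'   simulator or the bounding box of the data.
#' @return An `nt_clustering`: the input tibble with a `cluster` column (0 =
#'   noise / unclustered) plus attributes `hierarchy` (full-length label
#'   vectors per community level, coarsest first), `r_o` (initial and
#'   rebuilt) and `config`.
#' @export
#' @examples
#' gt <- generate_clustered_field(region_rect(4000, 4000), 5, 50, 25,
#'                                background_density = 2, seed = 3)
#' cl <- cluster_localizations(gt, pipeline_config(seed = 3))
#' table(cl$cluster)
cluster_localizations <- function(locs, config = pipeline_config(),
                                  region = NULL) {
  stopifnot(inherits(config, "nt_config"))
  locs <- as_tibble(locs)
  region <- region %||% attr(locs, "region") %||% bbox_region(locs)
  n <- nrow(locs)
  empty <- function() {
    out <- dplyr::mutate(locs, cluster = integer(n))
    structure(out, region = region, hierarchy = list(),
              r_o = c(initial = NA_real_, rebuilt = NA_real_),
              config = config, class = c("nt_clustering", class(out)))
  }
  if (n < config$K + 1) return(empty())

  # canonical ordering makes the labelling invariant to input row order
  ord <- order(locs$x, locs$y)
  xs <- locs$x[ord]; ys <- locs$y[ord]
  pts <- tibble(x = xs, y = ys)

  g1 <- build_knn_graph(pts, config$K)
  keep <- classify_noise(g1, config$alpha_sig, region,
                         n_simulations = config$noise_simulations,
                         seed = config$seed)
  labels_sorted <- integer(n)
  hierarchy <- list()
  r_o2 <- NA_real_
  if (sum(keep) >= max(config$K + 1, config$min_cluster_size)) {
    surv <- tibble(x = xs[keep], y = ys[keep])
    g2 <- build_knn_graph(surv, config$K)
    r_o2 <- g2$r_o
    hier <- detect_communities(g2, seed = config$seed)
    labs <- robust_merge(hier[[1]], g2)
    labs <- filter_min_size(labs, config$min_cluster_size)
    labels_sorted[keep] <- labs
    hierarchy <- lapply(hier, function(h) {
      full <- integer(n); full[keep] <- h
      out <- integer(n); out[ord] <- full
      out
    })
  }
  labels <- integer(n)
  labels[ord] <- labels_sorted

  out <- dplyr::mutate(locs, cluster = labels)
  structure(out, region = region, hierarchy = hierarchy,
            r_o = c(initial = g1$r_o, rebuilt = r_o2), config = config,
            class = c("nt_clustering", class(out)))
}

filter_min_size <- function(labels, min_size) {
  tab <- table(labels[labels > 0])
  small <- as.integer(names(tab)[tab < min_size])
  labels[labels %in% small] <- 0L
  relabel_contiguous(labels)
}

bbox_region <- function(locs) {
  region_rect(max(diff(range(locs$x)), 1), max(diff(range(locs$y)), 1),
              min(locs$x), min(locs$y))
}

#' @export
print.nt_clustering <- function(x, ...) {
  k <- length(setdiff(unique(x$cluster), 0L))
  cat(sprintf("<nanocluster labelling: %d localizations, %d clusters, %.1f%% clustered>\n",
              nrow(x), k, 100 * mean(x$cluster > 0)))
  NextMethod()
}
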