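# ggplot2 autoplot methods and broom-style tidiers.

#' Plot a nanocluster labelling
#'
#' Noise localizations in grey, clustered localizations coloured by cluster.
#'
#' @param object An `nt_clustering`.
#' @param point_size Point size.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nt_clustering <- function(object, point_size = 0.6, ...) {
  df <- as_tibble(object)
  df$label <- factor(ifelse(df$cluster > 0, df$cluster, NA))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(data = df[df$cluster == 0, ], colour = "grey70",
                        size = point_size) +
    ggplot2::geom_point(data = df[df$cluster > 0, ],
                        ggplot2::aes(colour = .data$label), size = point_size,
                        show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)",
                  title = sprintf("%d nanoclusters, %.1f%% clustered",
                                  length(setdiff(unique(df$cluster), 0L)),
                                  100 * mean(df$cluster > 0))) +
    ggplot2::theme_minimal()
}

#' Plot a G-function with its CSR envelope
#'
#' @param object An `nt_gfunction` (with or without envelope columns).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nt_gfunction <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$d))
  if (all(c("envelope_low", "envelope_high") %in% names(df))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$envelope_low, ymax = .data$envelope_high),
      fill = "grey80")
  }
  p + ggplot2::geom_line(ggplot2::aes(y = .data$G), colour = "steelblue") +
    ggplot2::labs(x = "d (nm)", y = "G(d)",
                  title = "Nearest-particle distance function") +
    ggplot2::theme_minimal()
}

#' Plot a photon-threshold scan
#'
#' @param object An `nt_threshold_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nt_threshold_scan <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df[df$evaluable, ],
                  ggplot2::aes(x = .data$threshold, y = .data$median_distance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "target_distance"),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = attr(object, "chosen_threshold"),
                        colour = "firebrick") +
    ggplot2::labs(x = "photon threshold",
                  y = "median Delaunay distance (nm)",
                  title = "Photon threshold scan") +
    ggplot2::theme_minimal()
}

#' Tidy a nanocluster labelling into per-cluster rows
#'
#' @param x An `nt_clustering`.
#' @param ... Unused.
#' @return Tibble with one row per cluster: `cluster`, `cx`, `cy`, `n`.
#' @export
tidy.nt_clustering <- function(x, ...) {
  cluster_centroids(x)
}

#' One-row summary of a nanocluster labelling
#'
#' @param x An `nt_clustering`.
#' @param ... Unused.
#' @return Tibble with `n_localizations`, `n_clusters`, `pct_clustered`,
#'   `r_o_initial`, `r_o_rebuilt`.
#' @export
glance.nt_clustering <- function(x, ...) {
  r_o <- attr(x, "r_o")
  tibble(
    n_localizations = nrow(x),
    n_clusters = length(setdiff(unique(x$cluster), 0L)),
    pct_clustered = 100 * mean(x$cluster > 0),
    r_o_initial = unname(r_o[["initial"]]),
    r_o_rebuilt = unname(r_o[["rebuilt"]])
  )
}

#' @rdname tidy.nt_clustering
#' @export
tidy.nt_gfunction <- function(x, ...) as_tibble(x)

#' @rdname tidy.nt_clustering
#' @export
tidy.nt_report <- function(x, ...) x$summary

#' @rdname glance.nt_clustering
#' @export
glance.nt_report <- function(x, ...) {
  dplyr::bind_cols(
    glance.nt_clustering(x$merged),
    tibble(max_clustering_distance = x$max_clustering_distance)
  )
}
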