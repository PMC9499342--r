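test_that("boundary area interpolates between convex hull and tight boundary", {
  sq <- tibble::tibble(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(cluster_area(sq, shrink = 0), 1)
  sq10 <- dplyr::mutate(sq, x = x * 10, y = y * 10)
  expect_equal(cluster_area(sq10, shrink = 0), 100)

  set.seed(40)
  disc <- blob(0, 0, n = 1000, r = 100)
  expect_lt(abs(cluster_area(disc, shrink = 0) - pi * 100^2) / (pi * 100^2),
            0.05)
  # tighter boundaries never exceed looser ones
  a <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(s) cluster_area(disc, s),
              numeric(1))
  expect_true(all(diff(a) <= 1e-9))

  expect_error(cluster_area(sq[1:2, ]), class = "nt_degenerate")
  col <- tibble::tibble(x = c(0, 1, 2), y = c(0, 0, 0))
  expect_error(cluster_area(col), class = "nt_degenerate")
})

test_that("farthest-pair ellipse fit is exact on constructed sets and rigid-motion invariant", {
  pts <- tibble::tibble(x = c(0, 4, 2, 2), y = c(0, 0, 1, -1))
  e <- ellipse_fit(pts)
  expect_equal(e$a, 2)
  expect_equal(e$b, 1)
  expect_equal(e$eccentricity, sqrt(0.75))

  th <- 30 * pi / 180
  rot <- tibble::tibble(x = pts$x * cos(th) - pts$y * sin(th) + 13,
                        y = pts$x * sin(th) + pts$y * cos(th) - 7)
  er <- ellipse_fit(rot)
  expect_equal(er$a, e$a, tolerance = 1e-12)
  expect_equal(er$b, e$b, tolerance = 1e-12)
  expect_equal(er$eccentricity, e$eccentricity, tolerance = 1e-12)

  # points on a circle: eccentricity shrinks as the sample fills the circle
  ecc_on_circle <- function(n) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-1]
    ellipse_fit(tibble::tibble(x = cos(th), y = sin(th)))$eccentricity
  }
  expect_lt(ecc_on_circle(200), 0.2)
  expect_lt(ecc_on_circle(200), ecc_on_circle(8))

  expect_error(ellipse_fit(tibble::tibble(x = rep(1, 5), y = rep(2, 5))),
               class = "nt_degenerate")

  # direct least-squares cross-check on a well-sampled exact ellipse
  tt <- seq(0, 2 * pi, length.out = 41)[-1]
  ell <- tibble::tibble(x = 3 * cos(tt), y = 1 * sin(tt))
  lsq <- ellipse_fit_lsq(ell)
  expect_equal(lsq$a, 3, tolerance = 1e-6)
  expect_equal(lsq$b, 1, tolerance = 1e-6)
  geo <- ellipse_fit(ell)
  expect_equal(geo$a, 3, tolerance = 1e-6)
})

test_that("inter-centroid distances follow the Delaunay convention", {
  two <- tibble::tibble(x = c(rep(0, 3), rep(1500, 3)),
                        y = c(0, 10, -10, 0, 10, -10),
                        cluster = rep(1:2, each = 3))
  expect_equal(inter_centroid_distances(two), 1500, tolerance = 1e-9)

  # 4 centroids on a unit square: 4 sides and one diagonal
  sq <- tibble::tibble(x = c(0, 1000, 1000, 0), y = c(0, 0, 1000, 1000),
                       cluster = 1:4)
  d <- sort(inter_centroid_distances(sq))
  expect_equal(length(d), 5)
  expect_equal(d[1:4], rep(1000, 4), tolerance = 1e-9)
  expect_equal(d[5], 1000 * sqrt(2), tolerance = 1e-9)
  expect_true(all(d <= 1000 * sqrt(2) + 1e-9))

  one <- tibble::tibble(x = 0, y = 0, cluster = 1)
  expect_equal(inter_centroid_distances(one), numeric(0))
})

test_that("region partitioning tags peripheral and central points disjointly", {
  th <- seq(0, 2 * pi, length.out = 65)[-1]
  cell <- tibble::tibble(x = 5000 * cos(th), y = 5000 * sin(th))
  pts <- tibble::tibble(x = c(4750, 0, 3000, 6000), y = 0)
  tags <- suppressMessages(partition_regions(pts, cell))
  expect_equal(tags, c("peripheral", "central", "intermediate", "outside"))
  expect_false(any(tags == "peripheral" & tags == "central"))
  expect_error(partition_regions(pts, cell[1:2, ]),
               class = "nt_invalid_parameter")
})

test_that("cluster summaries report medians with CIs and exact densities", {
  set.seed(44)
  gt <- generate_clustered_field(region_rect(6000, 6000), 8, 50, 25,
                                 background_density = 0, seed = 44)
  cl <- cluster_localizations(gt, test_config(seed = 44))
  met <- summarize_clusters(cl, shrink = 0)
  # density is n/area by construction
  ok <- with(met$clusters,
             abs(density_per_um2 - n / area_nm2 * 1e6) < 1e-9)
  expect_true(all(ok, na.rm = TRUE))
  # no background: (almost) everything sits in clusters
  pct <- met$summary$median[met$summary$metric ==
                              "pct_localizations_in_nanoclusters"]
  expect_gt(pct, 95)
  # recovered occupancy and area scales match the planted geometry
  mol <- met$summary$median[met$summary$metric ==
                              "localizations_per_nanocluster"]
  expect_true(mol >= 20 && mol <= 27)
  # Monte-Carlo oracle: expected convex-hull area of 25 uniform-disc points
  hull_area_mc <- mean(replicate(200, {
    p <- blob(0, 0, 25, 50)
    h <- grDevices::chull(p$x, p$y)
    abs(sum(p$x[h] * p$y[c(h[-1], h[1])] - p$x[c(h[-1], h[1])] * p$y[h])) / 2
  }))
  area <- met$summary$median[met$summary$metric == "nanocluster_area"]
  expect_lt(abs(area - hull_area_mc) / hull_area_mc, 0.3)
  expect_true(all(c("pct_localizations_in_nanoclusters", "nanocluster_area",
                    "molecule_density", "localizations_per_nanocluster",
                    "inter_centroid_distance") %in% met$summary$metric))
  expect_identical(tidy(met), met$summary)
})

test_that("label-contrast fields reproduce the crosslinking direction of effects", {
  # crosslinked-like: denser, more molecules per cluster; monovalent-like:
  # sparser, larger clusters. The summary must order percent clustered and
  # density accordingly.
  region <- region_rect(8000, 8000)
  mono <- generate_clustered_field(region, 10, 60, 20,
                                   background_density = 10, seed = 45)
  cross <- generate_clustered_field(region, 14, 40, 30,
                                    background_density = 4, seed = 46)
  sm <- summarize_clusters(cluster_localizations(mono, test_config(seed = 45)))
  sc <- summarize_clusters(cluster_localizations(cross, test_config(seed = 46)))
  med <- function(s, m) s$summary$median[s$summary$metric == m]
  expect_gt(med(sc, "pct_localizations_in_nanoclusters"),
            med(sm, "pct_localizations_in_nanoclusters"))
  expect_gt(med(sc, "molecule_density"), med(sm, "molecule_density"))
})
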