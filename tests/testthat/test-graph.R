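test_that("length scale is the median K-th NN distance and scales linearly", {
  grid4 <- tibble::tibble(x = c(0, 1, 0, 1) * 100, y = c(0, 0, 1, 1) * 100)
  expect_equal(estimate_length_scale(grid4, K = 1), 100)
  expect_equal(estimate_length_scale(dplyr::mutate(grid4, x = x * 3, y = y * 3),
                                     K = 1), 300)

  set.seed(17)
  p <- generate_csr(region_rect(10000, 10000), 50, seed = 17)
  r_o <- estimate_length_scale(p, K = 10)
  # oracle: median 10th-NN distance from the full distance matrix
  D <- as.matrix(dist(cbind(p$x, p$y))); diag(D) <- Inf
  kth <- apply(D, 1, function(r) sort(r)[10])
  expect_equal(r_o, median(kth), tolerance = 1e-12)

  expect_error(estimate_length_scale(grid4, K = 5),
               class = "nt_invalid_parameter")
})

test_that("kNN graph uses the union rule and Gaussian kernel weights", {
  two <- tibble::tibble(x = c(0, 100), y = c(0, 0))
  g <- build_knn_graph(two, K = 1, r_o = 100)
  expect_equal(igraph::ecount(g$graph), 1)
  expect_equal(igraph::E(g$graph)$weight, exp(-1))

  dup <- tibble::tibble(x = c(0, 0, 500), y = c(0, 0, 0))
  gd <- build_knn_graph(dup, K = 1, r_o = 100)
  ed <- graph_edges(gd)
  expect_equal(ed$weight[ed$dist == 0], 1)

  set.seed(18)
  p <- blob(0, 0, n = 120, r = 300)
  gp <- build_knn_graph(p, K = 10)
  expect_lte(igraph::ecount(gp$graph), nrow(p) * 10)
  # every edge endpoint pair satisfies the kNN adjacency rule
  kn <- nanotopo:::nt_knn(p$x, p$y, 10)
  el <- igraph::as_edgelist(gp$graph)
  ok <- vapply(seq_len(nrow(el)), function(r) {
    i <- el[r, 1]; j <- el[r, 2]
    j %in% kn$index[i, ] || i %in% kn$index[j, ]
  }, logical(1))
  expect_true(all(ok))
})

test_that("noise classification is calibrated on CSR and sensitive to clusters", {
  region <- region_rect(6000, 6000)
  csr <- generate_csr(region, 60, seed = 19)
  g <- build_knn_graph(csr, K = 10)
  keep <- classify_noise(g, 0.05, region, n_simulations = 20, seed = 19)
  # clustered fraction at most alpha within Monte-Carlo error
  se <- sqrt(0.05 * 0.95 / nrow(csr))
  expect_lte(mean(keep), 0.05 + 3 * se)

  # one dense cluster over sparse background: members survive
  set.seed(20)
  clus <- blob(3000, 3000, n = 30, r = 50)
  bg <- generate_csr(region, 3, seed = 20)
  pts <- dplyr::bind_rows(clus, tibble::tibble(x = bg$x, y = bg$y))
  g2 <- build_knn_graph(pts, K = 10)
  keep2 <- classify_noise(g2, 0.05, region, n_simulations = 20, seed = 20)
  expect_gte(mean(keep2[1:30]), 0.9)

  # alpha -> 1 classifies (almost) everything as clustered
  keep3 <- classify_noise(g, 0.99, region, n_simulations = 20, seed = 19)
  expect_gte(mean(keep3), 0.9)
})

test_that("community detection separates blobs and returns a hierarchy", {
  set.seed(21)
  pts <- dplyr::bind_rows(blob(0, 0, 40, 50), blob(5000, 0, 40, 50))
  g <- build_knn_graph(pts, K = 10)
  hier <- detect_communities(g, seed = 21)
  for (lv in hier) {
    # no community ever mixes the two blobs (gap >> r_o), at any level;
    # modularity methods may split a dense blob internally, which the
    # robustness-gated merge below repairs
    expect_equal(length(intersect(lv[1:40], lv[41:80])), 0)
  }
  merged <- robust_merge(hier[[1]], g)
  expect_equal(length(unique(merged)), 2)
  expect_equal(length(unique(merged[1:40])), 1)
  expect_equal(length(unique(merged[41:80])), 1)

  clique <- igraph::make_full_graph(12)
  igraph::E(clique)$weight <- 1
  cg <- structure(list(graph = clique, r_o = 1, K = 11,
                       x = rep(0, 12), y = rep(0, 12)),
                  class = "nt_cluster_graph")
  expect_equal(length(unique(detect_communities(cg, seed = 1)[[1]])), 1)
})

test_that("robust merging requires two node-disjoint connecting paths", {
  # clusters {1,2,3} and {5,6,7} joined through the single bridge node 4
  bridge <- igraph::graph_from_edgelist(rbind(
    c(1, 2), c(2, 3), c(1, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 7), c(5, 7)),
    directed = FALSE)
  igraph::E(bridge)$weight <- 1
  cgb <- structure(list(graph = bridge, r_o = 1, K = 3,
                        x = 1:7, y = rep(0, 7)), class = "nt_cluster_graph")
  labs <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L)
  expect_equal(robust_merge(labs, cgb), labs) # articulation node blocks it

  # same clusters joined through two disjoint paths merge
  twopath <- igraph::add_edges(bridge, c(1, 7))
  igraph::E(twopath)$weight <- 1
  cgt <- structure(list(graph = twopath, r_o = 1, K = 3,
                        x = 1:7, y = rep(0, 7)), class = "nt_cluster_graph")
  expect_equal(length(unique(robust_merge(labs, cgt))), 1)

  # no inter-cluster edges: labelling unchanged
  two <- igraph::graph_from_edgelist(rbind(c(1, 2), c(3, 4)),
                                     directed = FALSE)
  igraph::E(two)$weight <- 1
  cg2 <- structure(list(graph = two, r_o = 1, K = 1,
                        x = 1:4, y = rep(0, 4)), class = "nt_cluster_graph")
  expect_equal(robust_merge(c(1L, 1L, 2L, 2L), cg2), c(1L, 1L, 2L, 2L))
})

test_that("the size filter and edge cases of the full clustering hold", {
  region <- region_rect(3000, 3000)
  # a single 14-member cluster falls below the minimum size of 15
  set.seed(22)
  small <- with_region(blob(1500, 1500, n = 14, r = 40), region)
  cl <- cluster_localizations(small, test_config(seed = 22), region = region)
  expect_equal(sum(cl$cluster > 0), 0)

  # 16 members pass
  big <- with_region(blob(1500, 1500, n = 16, r = 40), region)
  cl2 <- cluster_localizations(big, test_config(seed = 22), region = region)
  expect_equal(length(setdiff(unique(cl2$cluster), 0L)), 1)

  empty <- tibble::tibble(x = numeric(), y = numeric())
  cl3 <- cluster_localizations(empty, test_config(), region = region)
  expect_equal(nrow(cl3), 0)
  expect_s3_class(cl3, "nt_clustering")
})

test_that("clustering is deterministic, order- and scale-invariant", {
  gt <- generate_clustered_field(region_rect(4000, 4000), 5, 50, 25,
                                 background_density = 2, seed = 3)
  cfg <- test_config(seed = 3)
  c1 <- cluster_localizations(gt, cfg)
  c2 <- cluster_localizations(gt, cfg)
  expect_identical(c1$cluster, c2$cluster)

  set.seed(7)
  perm <- sample(nrow(gt))
  gtp <- with_region(gt[perm, ], attr(gt, "region"))
  c3 <- cluster_localizations(gtp, cfg)
  expect_identical(c1$cluster[perm], c3$cluster)

  gts <- with_region(dplyr::mutate(tibble::as_tibble(gt),
                                   x = .data$x * 3, y = .data$y * 3),
                     region_rect(12000, 12000))
  c4 <- cluster_localizations(gts, cfg)
  expect_identical(c1$cluster, c4$cluster)
})
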