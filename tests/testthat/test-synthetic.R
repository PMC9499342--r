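test_that("CSR generator draws a Poisson number of uniform points, reproducibly", {
  region <- region_rect(10000, 10000)
  expect_error(generate_csr(region, density = 0), class = "nt_invalid_parameter")
  expect_error(region_rect(0, 10000), class = "nt_invalid_parameter")

  # mean count over 100 seeds within 3 sigma of lambda = 50/um^2 * 100 um^2
  counts <- vapply(1:100, function(s) nrow(generate_csr(region, 50, seed = s)),
                   numeric(1))
  expect_lt(abs(mean(counts) - 5000), 3 * sqrt(5000) / sqrt(100))

  a <- generate_csr(region, 50, seed = 1)
  b <- generate_csr(region, 50, seed = 1)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_true(all(a$cluster_id == 0L))
  expect_true(all(region_contains(region, a$x, a$y)))
})

test_that("clustered fields respect geometry, counts and ground-truth ids", {
  region <- region_rect(10000, 10000)
  one <- generate_clustered_field(region, n_clusters = 1, cluster_radius = 50,
                                  molecules_per_cluster = 20, seed = 2)
  p <- attr(one, "cluster_params")
  expect_equal(nrow(one), 20)
  expect_true(all(one$cluster_id == 1L))
  expect_true(all(sqrt((one$x - p$cx)^2 + (one$y - p$cy)^2) <= 50))

  many <- generate_clustered_field(region, 20, 50, 25, background_density = 2,
                                   seed = 3)
  expect_setequal(unique(many$cluster_id[many$cluster_id > 0]), 1:20)
  # counting invariant: per-cluster counts plus background = total
  tab <- table(factor(many$cluster_id, levels = 0:20))
  expect_equal(sum(tab), nrow(many))
  expect_equal(as.integer(tab[as.character(1:20)]),
               attr(many, "cluster_params")$n_molecules)
  # exclusion zones of radius 2r do not overlap
  cen <- attr(many, "cluster_params")
  dd <- dist(cbind(cen$cx, cen$cy))
  expect_true(all(dd >= 4 * 50))

  expect_error(
    generate_clustered_field(region_rect(500, 500), 20, 50, 10, seed = 1),
    class = "nt_placement_failure")
})

test_that("disc-uniform clusters have mean centre distance 2r/3", {
  gt <- generate_clustered_field(region_rect(2000, 2000), 1, 50, 10000,
                                 seed = 4)
  p <- attr(gt, "cluster_params")
  d <- sqrt((gt$x - p$cx)^2 + (gt$y - p$cy)^2)
  # sd of the distance for a uniform disc is r * sqrt(1/18)
  se <- 50 * sqrt(1 / 18) / sqrt(10000)
  expect_lt(abs(mean(d) - 2 / 3 * 50), 4 * se)
})

test_that("blinking appearances follow the acquisition model", {
  region <- region_rect(5000, 5000)
  gt <- generate_csr(region, 100, seed = 5)
  exact <- acquisition_model(reappearance_rate = 1, photon_cv = 0,
                             loc_precision_sigma = 0)
  app <- simulate_appearances(gt, exact, seed = 5)
  expect_equal(nrow(app), nrow(gt))
  expect_setequal(app$molecule, gt$id)
  # zero localization noise: coordinates equal the truth
  expect_equal(sort(app$x), sort(gt$x))
  expect_true(all(app$photons == exact$mean_photons))
  expect_true(!is.unsorted(app$frame))

  big <- generate_csr(region_rect(20000, 20000), 25, seed = 6)
  noisy <- acquisition_model(reappearance_rate = 2)
  app2 <- simulate_appearances(big, noisy, seed = 6)
  rate_hat <- nrow(app2) / nrow(big)
  se <- 1 / sqrt(nrow(big)) # appearance count is 1 + Poisson(1)
  expect_lt(abs(rate_hat - 2), 3 * se)

  expect_error(acquisition_model(reappearance_rate = 0.5),
               class = "nt_invalid_parameter")
})

test_that("rendering conserves photons and places spots correctly", {
  mod <- acquisition_model(frames = 1, photon_cv = 0, loc_precision_sigma = 0,
                           reappearance_rate = 1, psf_sigma = 150,
                           pixel_size = 100, background_rate = 0,
                           camera_gain = 1)
  one <- tibble::tibble(id = 1L, frame = 1L, x = 1550, y = 1720,
                        photons = 1000)
  st <- render_frames(one, mod, region = region_rect(3200, 3200))
  expect_lt(abs(sum(st[[1]]) - 1000) / 1000, 0.005)

  none <- one[0, ]
  st0 <- render_frames(none, mod, region = region_rect(3200, 3200))
  expect_true(all(st0[[1]] == 0))

  two <- tibble::tibble(id = 1:2, frame = c(1L, 1L), x = c(850, 1850),
                        y = c(1050, 1050), photons = c(1000, 1000))
  st2 <- render_frames(two, mod, region = region_rect(3200, 3200))
  maxima <- which(nanotopo:::local_maxima_8(st2[[1]]) &
                    st2[[1]] > 0.5 * max(st2[[1]]))
  expect_equal(length(maxima), 2)

  expect_warning(
    render_frames(one, acquisition_model(frames = 1, psf_sigma = 5,
                                         pixel_size = 100),
                  region = region_rect(3200, 3200)),
    "undersampled")
})

test_that("mesoscale fields plant bright cores on the site grid", {
  f <- simulate_mesoscale_field(seed = 8)
  expect_equal(nrow(f$sted), nrow(f$sites))
  # bright localizations cluster near the sites, dim ones everywhere
  bright <- f$storm[f$storm$photons > 10000, ]
  d_site <- vapply(seq_len(nrow(bright)), function(i) {
    min(sqrt((f$sites$x - bright$x[i])^2 + (f$sites$y - bright$y[i])^2))
  }, numeric(1))
  expect_true(all(d_site < 500))
  f2 <- simulate_mesoscale_field(seed = 8)
  expect_identical(f$storm, f2$storm)
})
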