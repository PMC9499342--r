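test_that("STED spot detection finds rendered spots to sub-pixel accuracy", {
  flat <- matrix(5, 40, 40)
  expect_equal(nrow(detect_sted_spots(flat, 100)), 0)

  truth <- tibble::tibble(id = 1:3, frame = 1L,
                          x = c(800, 2000, 2700), y = c(900, 2500, 1300),
                          photons = 3000)
  mod <- acquisition_model(frames = 1, psf_sigma = 150, pixel_size = 100,
                           background_rate = 5)
  st <- render_frames(truth, mod, region = region_rect(3500, 3500),
                      mode = "sted", spot_sigma = 200, shot_noise = TRUE,
                      seed = 5)
  sp <- detect_sted_spots(st[[1]], pixel_size = 100)
  expect_equal(nrow(sp), 3)
  for (i in 1:3) {
    err <- min(sqrt((sp$x - truth$x[i])^2 + (sp$y - truth$y[i])^2))
    expect_lt(err, 0.5 * 100) # within half a pixel
  }

  # two spots fused into one connected component give one joint particle
  close2 <- tibble::tibble(id = 1:2, frame = 1L, x = c(1000, 1250),
                           y = c(1000, 1000), photons = 3000)
  stc <- render_frames(close2, mod, region = region_rect(2000, 2000),
                       mode = "sted", spot_sigma = 200)
  spc <- detect_sted_spots(stc[[1]], pixel_size = 100)
  expect_equal(nrow(spc), 1)
  expect_lt(abs(spc$x - 1125), 100) # joint centroid between the two
})

test_that("STORM frame fitting localizes a single emitter accurately", {
  mod <- acquisition_model(frames = 1, mean_photons = 5000, photon_cv = 0,
                           loc_precision_sigma = 0, reappearance_rate = 1,
                           psf_sigma = 150, pixel_size = 100,
                           background_rate = 10)
  one <- tibble::tibble(id = 1L, frame = 1L, x = 1030, y = 1270,
                        photons = 5000)
  st <- render_frames(one, mod, region = region_rect(3200, 3200),
                      shot_noise = TRUE, seed = 4)
  p <- fit_storm_frame(st[[1]], psf_sigma = 150, pixel_size = 100)
  expect_equal(nrow(p), 1)
  expect_lt(sqrt((p$x - 1030)^2 + (p$y - 1270)^2), 0.1 * 100)
  expect_lt(abs(p$photons - 5000) / 5000, 0.10)

  empty <- matrix(rpois(32 * 32, 10), 32, 32)
  expect_equal(nrow(fit_storm_frame(empty, 150, 100, threshold_factor = 3)), 0)
})

test_that("localization precision approaches the photon-limited bound", {
  # repeated fits of the same emitter: per-axis sd should match
  # psf_sigma / sqrt(N) within a factor 1.5 (pixelation adds a little)
  mod <- acquisition_model(frames = 1, mean_photons = 5000, photon_cv = 0,
                           loc_precision_sigma = 0, reappearance_rate = 1,
                           psf_sigma = 150, pixel_size = 100,
                           background_rate = 2)
  one <- tibble::tibble(id = 1L, frame = 1L, x = 1030, y = 1270,
                        photons = 5000)
  set.seed(99)
  xs <- replicate(60, {
    st <- render_frames(one, mod, region = region_rect(2100, 2100),
                        shot_noise = TRUE)
    p <- fit_storm_frame(st[[1]], psf_sigma = 150, pixel_size = 100,
                         threshold_factor = 2)
    if (nrow(p) == 1) p$x else NA_real_
  })
  xs <- xs[!is.na(xs)]
  expect_gt(length(xs), 50)
  theory <- 150 / sqrt(5000)
  expect_lt(sd(xs), 1.5 * theory)
  expect_gt(sd(xs), theory / 1.5)
})

test_that("multi-emitter filtering rejects wide elliptical joint fits", {
  mod <- acquisition_model(frames = 1, mean_photons = 5000, photon_cv = 0,
                           loc_precision_sigma = 0, reappearance_rate = 1,
                           psf_sigma = 150, pixel_size = 100,
                           background_rate = 5)
  # two emitters just under 2*psf_sigma apart appear as one elongated peak
  pair <- tibble::tibble(id = 1:2, frame = 1L, x = c(1000, 1280),
                         y = c(1000, 1000), photons = 5000)
  st <- render_frames(pair, mod, region = region_rect(2100, 2100),
                      shot_noise = TRUE, seed = 12)
  p <- fit_storm_frame(st[[1]], psf_sigma = 150, pixel_size = 100)
  expect_gte(nrow(p), 1)
  kept <- filter_multi_emitter(p, max_ellipticity = 1.3,
                               sigma_range = c(0.5, 2) * 150)
  expect_equal(nrow(kept), 0) # the joint peak is rejected

  # an isolated emitter passes, and an unbounded filter is the identity
  single <- tibble::tibble(id = 1L, frame = 1L, x = 1000, y = 1000,
                           photons = 5000)
  st1 <- render_frames(single, mod, region = region_rect(2100, 2100),
                       shot_noise = TRUE, seed = 13)
  p1 <- fit_storm_frame(st1[[1]], psf_sigma = 150, pixel_size = 100)
  expect_equal(nrow(filter_multi_emitter(p1, 1.3, c(0.5, 2) * 150)), nrow(p1))
  expect_identical(nrow(filter_multi_emitter(p, Inf)), nrow(p))
})

test_that("chain-link grouping respects displacement, gaps and tie rule", {
  parts <- tibble::tibble(
    frame = c(5L, 6L, 7L, 5L, 8L),
    x = c(1000, 1010, 995, 5000, 5005),
    y = c(1000, 1005, 1010, 5000, 5002),
    photons = c(100, 300, 100, 200, 50)
  )
  g <- group_time_contiguous(parts, pixel_size = 100)
  # frames 5,6,7 at small displacements chain into one group
  expect_equal(length(unique(g$group[g$x < 2000])), 1)
  # frame gap 5 -> 8 breaks the chain
  expect_equal(length(unique(g$group[g$x > 2000])), 2)

  # tie rule: joins the nearer of two previous-frame candidates
  tie <- tibble::tibble(
    frame = c(1L, 1L, 2L),
    x = c(0, 80, 30), y = c(0, 0, 0), photons = 1
  )
  gt <- group_time_contiguous(tie, pixel_size = 100)
  expect_equal(gt$group[gt$frame == 2], gt$group[gt$x == 0 & gt$frame == 1])
})

test_that("photon-weighted merging conserves photons and positions", {
  g <- tibble::tibble(frame = c(1L, 1L), x = c(0, 3), y = c(0, 0),
                      photons = c(100, 300), group = c(1L, 1L))
  m <- merge_weighted(g)
  expect_equal(m$x, 2.25)
  expect_equal(m$photons, 400)

  single <- tibble::tibble(frame = 2L, x = 5, y = 7, photons = 50, group = 1L)
  ms <- merge_weighted(single)
  expect_equal(ms[, c("x", "y", "photons")],
               single[, c("x", "y", "photons")])

  k_same <- tibble::tibble(frame = rep(1L, 4), x = rep(2, 4), y = rep(3, 4),
                           photons = rep(10, 4), group = rep(1L, 4))
  mk <- merge_weighted(k_same)
  expect_equal(mk$x, 2)
  expect_equal(mk$photons, 40)

  zero <- tibble::tibble(frame = 1L, x = 0, y = 0, photons = 0, group = 1L)
  expect_error(merge_weighted(zero), class = "nt_invalid_parameter")
})

test_that("grouping partitions the input and recovers molecule counts", {
  # contiguous-blink fixture: every molecule appears in consecutive frames
  set.seed(41)
  n_mol <- 200
  mol <- tibble::tibble(x = runif(n_mol, 0, 20000), y = runif(n_mol, 0, 20000))
  rows <- lapply(seq_len(n_mol), function(i) {
    k <- 1 + rpois(1, 0.8)
    f0 <- sample.int(500, 1)
    tibble::tibble(frame = f0:(f0 + k - 1),
                   x = mol$x[i] + rnorm(k, 0, 10),
                   y = mol$y[i] + rnorm(k, 0, 10),
                   photons = rlnorm(k, 8, 0.4))
  })
  parts <- dplyr::bind_rows(rows)
  g <- group_time_contiguous(parts, pixel_size = 100)
  expect_equal(sum(table(g$group)), nrow(parts)) # a partition
  m <- merge_weighted(g)
  expect_equal(sum(m$photons), sum(parts$photons))
  expect_lt(abs(nrow(m) / n_mol - 1), 0.10)
})
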