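# Synthetic localization fields with known ground truth.
#
# Raw single-molecule data for this kind of experiment are rarely deposited,
# so every downstream stage is exercised against simulated fields: clustered
# molecule positions over a CSR background, stochastic blinking re-appearances
# with localization noise and lognormal photon counts, and rendered
# Gaussian-PSF frame stacks.

new_ground_truth <- function(molecules, region, cluster_params) {
  structure(
    molecules,
    region = region,
    cluster_params = cluster_params,
    class = c("nt_ground_truth", class(tibble())))
}

#' @export
print.nt_ground_truth <- function(x, ...) {
  cat(sprintf("<ground truth: %d molecules, %d clusters, %d background>\n",
              nrow(x), length(unique(x$cluster_id[x$cluster_id > 0])),
              sum(x$cluster_id == 0)))
  NextMethod()
}

#' Simulate a completely spatially random (CSR) molecule field
#'
#' Draws a homogeneous Poisson point process over a region: the number of
#' molecules is Poisson with mean `density * area` and positions are uniform.
#' CSR fields are the null model against which clustering is calibrated and
#' tested.
#'
#' @param region A [region_rect()] or [region_disc()].
#' @param density Expected molecules per um^2 (note: per square micrometre,
#'   the field's customary unit; coordinates themselves are in nm).
#' @param seed Integer seed; identical seeds give identical fields.
#' @return A ground-truth tibble with columns `id`, `x`, `y` (nm) and
#'   `cluster_id` (all 0 = background), carrying the region as an attribute.
#' @export
#' @examples
#' gt <- generate_csr(region_rect(10000, 10000), density = 50, seed = 1)
#' nrow(gt)
generate_csr <- function(region, density, seed = NULL) {
  if (!inherits(region, "nt_region")) abort("region must be an nt_region")
  if (!is.finite(density) || density <= 0) {
    abort("density must be positive (molecules per um^2)",
          class = "nt_invalid_parameter")
  }
  if (!is.null(seed)) set.seed(seed)
  area_um2 <- region_area(region) / 1e6
  n <- rpois(1, density * area_um2)
  pos <- region_sample(region, n)
  mol <- tibble(id = seq_len(n), x = pos$x, y = pos$y,
                cluster_id = rep(0L, n))
  new_ground_truth(mol, region,
                   tibble(cluster_id = integer(), cx = numeric(),
                          cy = numeric(), radius = numeric(),
                          n_molecules = integer()))
}

#' Simulate a clustered molecule field over CSR background
#'
#' Plants `n_clusters` disc-shaped nanoclusters (optionally elongated via
#' `axis_ratio`) whose exclusion zones (discs of radius `2 * cluster_radius`)
#' neither overlap each other nor cross the region boundary, then adds a CSR
#' background. Defaults mirror the nanocluster scales reported for
#' receptor-labelled membranes: ~20-25 molecules in clusters a few tens of
#' nm in radius.
#'
#' @param region A [region_rect()] or [region_disc()].
#' @param n_clusters Number of planted nanoclusters.
#' @param cluster_radius Disc radius in nm (semi-major axis when
#'   `axis_ratio > 1`).
#' @param molecules_per_cluster Either a single count used for every cluster
#'   or a function `f(n_clusters)` returning one count per cluster.
#' @param background_density CSR background in molecules per um^2 (0 = none).
#' @param axis_ratio Major/minor axis ratio; 1 (default) gives circular
#'   clusters, larger values elongated ones with random orientation.
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling budget for placing cluster centres.
#' @return Ground-truth tibble (`id`, `x`, `y`, `cluster_id`; background has
#'   `cluster_id = 0`) with `region` and per-cluster `cluster_params`
#'   attributes.
#' @export
#' @examples
#' gt <- generate_clustered_field(region_rect(10000, 10000),
#'   n_clusters = 20, cluster_radius = 50,
#'   molecules_per_cluster = 25, background_density = 2, seed = 7)
#' table(gt$cluster_id > 0)
generate_clustered_field <- function(region, n_clusters, cluster_radius,
                                     molecules_per_cluster,
                                     background_density = 0,
                                     axis_ratio = 1,
                                     seed = NULL,
                                     max_attempts = 10000) {
  if (!inherits(region, "nt_region")) abort("region must be an nt_region")
  if (n_clusters < 0 || cluster_radius <= 0 || axis_ratio < 1) {
    abort("invalid cluster parameters", class = "nt_invalid_parameter")
  }
  if (!is.null(seed)) set.seed(seed)

  counts <- if (is.function(molecules_per_cluster)) {
    as.integer(molecules_per_cluster(n_clusters))
  } else {
    rep(as.integer(molecules_per_cluster), n_clusters)
  }
  stopifnot(length(counts) == n_clusters)

  excl <- 2 * cluster_radius
  centers <- matrix(numeric(0), ncol = 2)
  attempts <- 0
  while (nrow(centers) < n_clusters) {
    attempts <- attempts + 1
    if (attempts > max_attempts) {
      abort(sprintf(
        "could not place %d non-overlapping clusters after %d attempts",
        n_clusters, max_attempts), class = "nt_placement_failure")
    }
    cand <- region_sample(shrink_region(region, excl), 1)
    if (nrow(centers) == 0 ||
        all((centers[, 1] - cand$x)^2 + (centers[, 2] - cand$y)^2 >= (2 * excl)^2)) {
      centers <- rbind(centers, c(cand$x, cand$y))
    }
  }

  mols <- purrr::map(seq_len(n_clusters), function(k) {
    n <- counts[k]
    r <- cluster_radius * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    px <- r * cos(th)
    py <- r * sin(th) / axis_ratio
    rot <- runif(1, 0, pi)
    tibble(
      x = centers[k, 1] + px * cos(rot) - py * sin(rot),
      y = centers[k, 2] + px * sin(rot) + py * cos(rot),
      cluster_id = rep(k, n)
    )
  })
  mol <- dplyr::bind_rows(mols)

  if (background_density > 0) {
    bg <- generate_csr(region, background_density)
    mol <- dplyr::bind_rows(mol, tibble(x = bg$x, y = bg$y,
                                        cluster_id = rep(0L, nrow(bg))))
  }
  mol <- dplyr::mutate(mol, id = dplyr::row_number(), .before = 1)

  params <- tibble(
    cluster_id = seq_len(n_clusters),
    cx = centers[, 1], cy = centers[, 2],
    radius = cluster_radius, n_molecules = counts
  )
  new_ground_truth(mol, region, params)
}

# inset a region so that discs of radius `margin` around sampled points stay
# inside the original region
shrink_region <- function(region, margin) {
  if (region$shape == "rect") {
    w <- (region$xmax - region$xmin) - 2 * margin
    h <- (region$ymax - region$ymin) - 2 * margin
    if (w <= 0 || h <= 0) abort("region too small for requested clusters",
                                class = "nt_placement_failure")
    region_rect(w, h, region$xmin + margin, region$ymin + margin)
  } else {
    if (region$r <= margin) abort("region too small for requested clusters",
                                  class = "nt_placement_failure")
    region_disc(region$cx, region$cy, region$r - margin)
  }
}

#' Acquisition model for simulated localization microscopy
#'
#' Bundles the photophysical and optical parameters used by
#' [simulate_appearances()] and [render_frames()].
#'
#' @param frames Number of camera frames in the acquisition.
#' @param mean_photons Mean photons per localization event.
#' @param photon_cv Coefficient of variation of the (lognormal) photon count;
#'   0 gives a constant count.
#' @param loc_precision_sigma Isotropic localization noise sd in nm.
#' @param reappearance_rate Expected number of appearances per molecule
#'   (>= 1); blinking re-appearances model the overcounting inherent to
#'   reconstruction-based nanoscopy.
#' @param psf_sigma Gaussian PSF sd in nm used for rendering.
#' @param pixel_size Camera pixel size in nm.
#' @param background_rate Mean background photons per pixel per frame.
#' @param camera_gain Photons per digital unit.
#' @return An `nt_acquisition` parameter list.
#' @export
acquisition_model <- function(frames = 1000,
                              mean_photons = 5000,
                              photon_cv = 0.5,
                              loc_precision_sigma = 10,
                              reappearance_rate = 1.5,
                              psf_sigma = 150,
                              pixel_size = 100,
                              background_rate = 0,
                              camera_gain = 1) {
  vals <- c(frames = frames, mean_photons = mean_photons,
            loc_precision_sigma = loc_precision_sigma,
            reappearance_rate = reappearance_rate,
            psf_sigma = psf_sigma, pixel_size = pixel_size,
            camera_gain = camera_gain)
  if (any(!is.finite(vals)) || any(vals[c("frames", "mean_photons", "psf_sigma",
                                          "pixel_size", "camera_gain")] <= 0)) {
    abort("acquisition parameters must be positive and finite",
          class = "nt_invalid_parameter")
  }
  if (reappearance_rate < 1) {
    abort("reappearance_rate must be >= 1 (every molecule appears at least once)",
          class = "nt_invalid_parameter")
  }
  if (photon_cv < 0 || loc_precision_sigma < 0 || background_rate < 0) {
    abort("photon_cv, loc_precision_sigma and background_rate must be >= 0",
          class = "nt_invalid_parameter")
  }
  structure(list(frames = frames, mean_photons = mean_photons,
                 photon_cv = photon_cv,
                 loc_precision_sigma = loc_precision_sigma,
                 reappearance_rate = reappearance_rate,
                 psf_sigma = psf_sigma, pixel_size = pixel_size,
                 background_rate = background_rate,
                 camera_gain = camera_gain),
            class = "nt_acquisition")
}

#' Simulate blinking appearances of ground-truth molecules
#'
#' Each molecule appears `1 + Poisson(reappearance_rate - 1)` times (so every
#' molecule is seen at least once while overcounting is still modelled), in
#' uniformly random frames, with isotropic Gaussian localization noise and a
#' lognormal photon count parameterized by mean and coefficient of variation.
#'
#' @param truth Ground truth from [generate_csr()] or
#'   [generate_clustered_field()].
#' @param model An [acquisition_model()].
#' @param seed Integer seed.
#' @return A localization table (tibble) sorted by frame with columns `id`,
#'   `frame`, `x`, `y`, `photons`, `sigma`, plus provenance columns
#'   `molecule` and `true_cluster`.
#' @export
simulate_appearances <- function(truth, model, seed = NULL) {
  stopifnot(inherits(truth, "nt_ground_truth"), inherits(model, "nt_acquisition"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  k <- 1L + rpois(n, model$reappearance_rate - 1)
  mol_idx <- rep(seq_len(n), k)
  m <- length(mol_idx)
  if (model$photon_cv > 0) {
    sdlog <- sqrt(log(1 + model$photon_cv^2))
    meanlog <- log(model$mean_photons) - sdlog^2 / 2
    photons <- rlnorm(m, meanlog, sdlog)
  } else {
    photons <- rep(model$mean_photons, m)
  }
  out <- tibble(
    frame = sample.int(model$frames, m, replace = TRUE),
    x = truth$x[mol_idx] + rnorm(m, 0, model$loc_precision_sigma),
    y = truth$y[mol_idx] + rnorm(m, 0, model$loc_precision_sigma),
    photons = photons,
    sigma = rep(model$psf_sigma, m),
    molecule = truth$id[mol_idx],
    true_cluster = truth$cluster_id[mol_idx]
  )
  out <- dplyr::arrange(out, .data$frame)
  out <- dplyr::mutate(out, id = dplyr::row_number(), .before = 1)
  attr(out, "region") <- attr(truth, "region")
  out
}

#' Render localization appearances into camera frames
#'
#' Each appearance is drawn as an integrated 2D Gaussian whose pixel sum
#' equals `photons / camera_gain` (up to boundary truncation); Poisson
#' background is added per pixel. In `mode = "sted"` all appearances are
#' rendered into a single image with spot width `spot_sigma`, emulating a
#' directly acquired (targeted) nanoscopy image rather than a blinking stack.
#'
#' Pixel convention: x runs along columns, y along rows, origin at the
#' top-left corner of pixel (1,1); the centre of pixel (i, j) is at
#' ((j - 0.5) * pixel_size, (i - 0.5) * pixel_size).
#'
#' @param locs Localization table with `frame`, `x`, `y`, `photons`.
#' @param model An [acquisition_model()].
#' @param region Imaged region (defaults to the region attribute of `locs`).
#' @param mode `"storm"` (per-frame stack) or `"sted"` (single image).
#' @param spot_sigma Spot sd in nm for STED mode (defaults to `2 * psf_sigma`).
#' @param shot_noise If `TRUE`, per-pixel signal is Poisson-sampled instead of
#'   rendered at its expectation (needed to study fitting precision).
#' @param seed Integer seed for background/shot noise.
#' @return A list of numeric matrices (class `nt_image_stack`) with
#'   `pixel_size` attribute.
#' @export
render_frames <- function(locs, model, region = NULL,
                          mode = c("storm", "sted"), spot_sigma = NULL,
                          shot_noise = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "nt_acquisition"))
  region <- region %||% attr(locs, "region")
  if (is.null(region)) abort("no region supplied or attached to locs")
  if (region$shape != "rect") abort("rendering requires a rectangular region")
  if (!is.null(seed)) set.seed(seed)

  px <- model$pixel_size
  sig <- if (mode == "sted") (spot_sigma %||% (2 * model$psf_sigma)) else model$psf_sigma
  if (sig < px / 10) {
    warn("PSF sigma is less than pixel_size/10: rendered spots are undersampled")
  }
  ncol_px <- max(1L, ceiling((region$xmax - region$xmin) / px))
  nrow_px <- max(1L, ceiling((region$ymax - region$ymin) / px))

  render_one <- function(rows) {
    img <- matrix(0, nrow_px, ncol_px)
    if (nrow(rows) > 0) {
      xe <- region$xmin + (0:ncol_px) * px
      ye <- region$ymin + (0:nrow_px) * px
      for (r in seq_len(nrow(rows))) {
        # restrict to a +-5 sigma window
        jr <- which(xe[-1] > rows$x[r] - 5 * sig & xe[-(ncol_px + 1)] < rows$x[r] + 5 * sig)
        ir <- which(ye[-1] > rows$y[r] - 5 * sig & ye[-(nrow_px + 1)] < rows$y[r] + 5 * sig)
        if (length(jr) == 0 || length(ir) == 0) next
        fx <- diff(stats::pnorm(xe[c(jr, max(jr) + 1)], rows$x[r], sig))
        fy <- diff(stats::pnorm(ye[c(ir, max(ir) + 1)], rows$y[r], sig))
        img[ir, jr] <- img[ir, jr] +
          (rows$photons[r] / model$camera_gain) * (fy %o% fx)
      }
    }
    if (shot_noise) img[] <- rpois(length(img), pmax(img, 0))
    if (model$background_rate > 0) {
      img <- img + matrix(rpois(nrow_px * ncol_px,
                                model$background_rate / model$camera_gain),
                          nrow_px, ncol_px)
    }
    img
  }

  frames <- if (mode == "sted") {
    list(render_one(locs))
  } else {
    purrr::map(seq_len(model$frames), function(f) {
      render_one(locs[locs$frame == f, , drop = FALSE])
    })
  }
  structure(frames, pixel_size = px, region = region,
            class = "nt_image_stack")
}

#' @export
print.nt_image_stack <- function(x, ...) {
  cat(sprintf("<image stack: %d frame(s), %d x %d px, pixel %g nm>\n",
              length(x), nrow(x[[1]]), ncol(x[[1]]), attr(x, "pixel_size")))
  invisible(x)
}

#' Simulate a field with photon-correlated mesoscale structure
#'
#' Emulates the situation where the brightest localizations trace a coarser
#' (mesoscale) organization than the nanocluster lattice: ordinary dim
#' nanoclusters sit on a jittered grid with `cluster_spacing` pitch, while
#' "core" sites on a much coarser grid (`site_spacing`, micrometre scale)
#' additionally carry a few very bright localizations. A matching synthetic
#' STED particle set (one spot per site) is returned as the cross-modality
#' reference.
#'
#' @param region Rectangular region (default 10 x 10 um).
#' @param site_spacing Mesoscale site grid pitch in nm.
#' @param cluster_spacing Nanocluster grid pitch in nm.
#' @param cluster_radius Nanocluster disc radius in nm.
#' @param locs_per_cluster Dim localizations per nanocluster.
#' @param bright_per_site Bright localizations added at each site's core
#'   cluster.
#' @param dim_photons,bright_photons Lognormal mean photon counts.
#' @param photon_cv Coefficient of variation of photon counts.
#' @param seed Integer seed.
#' @return List with `storm` (localization tibble with photons; region
#'   attached), `sted` (tibble of site spot positions) and `sites` (planted
#'   site centres).
#' @export
simulate_mesoscale_field <- function(region = region_rect(10000, 10000),
                                     site_spacing = 3300,
                                     cluster_spacing = 400,
                                     cluster_radius = 50,
                                     locs_per_cluster = 20,
                                     bright_per_site = 3,
                                     dim_photons = 3000,
                                     bright_photons = 18000,
                                     photon_cv = 0.3,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(region$shape == "rect", site_spacing > cluster_spacing)
  gx <- seq(region$xmin + cluster_spacing / 2, region$xmax - cluster_spacing / 2,
            by = cluster_spacing)
  gy <- seq(region$ymin + cluster_spacing / 2, region$ymax - cluster_spacing / 2,
            by = cluster_spacing)
  centers <- expand.grid(cx = gx, cy = gy)
  jit <- cluster_spacing / 8
  centers$cx <- centers$cx + runif(nrow(centers), -jit, jit)
  centers$cy <- centers$cy + runif(nrow(centers), -jit, jit)

  sx <- seq(region$xmin + site_spacing / 2, region$xmax - site_spacing / 2,
            by = site_spacing)
  sy <- seq(region$ymin + site_spacing / 2, region$ymax - site_spacing / 2,
            by = site_spacing)
  sites <- expand.grid(x = sx, y = sy)

  draw_photons <- function(n, mean) {
    if (photon_cv > 0) {
      sdlog <- sqrt(log(1 + photon_cv^2))
      rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
    } else rep(mean, n)
  }
  disc <- function(cx, cy, n, photons_mean) {
    r <- cluster_radius * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
    tibble(x = cx + r * cos(th), y = cy + r * sin(th),
           photons = draw_photons(n, photons_mean))
  }

  dim_locs <- purrr::map(seq_len(nrow(centers)), function(i) {
    disc(centers$cx[i], centers$cy[i], locs_per_cluster, dim_photons)
  }) |> dplyr::bind_rows()

  core_idx <- vapply(seq_len(nrow(sites)), function(s) {
    which.min((centers$cx - sites$x[s])^2 + (centers$cy - sites$y[s])^2)
  }, integer(1))
  bright_locs <- purrr::map(core_idx, function(i) {
    disc(centers$cx[i], centers$cy[i], bright_per_site, bright_photons)
  }) |> dplyr::bind_rows()

  storm <- dplyr::bind_rows(dim_locs, bright_locs) |>
    dplyr::mutate(frame = 1L, id = dplyr::row_number(), .before = 1)
  attr(storm, "region") <- region
  sted <- tibble(x = centers$cx[core_idx], y = centers$cy[core_idx])
  list(storm = storm, sted = sted, sites = as_tibble(sites))
}

#' Write an image stack as multi-page TIFF
#'
#' @param stack An `nt_image_stack`.
#' @param path Output file.
#' @export
write_image_stack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required to write TIFF stacks")
  }
  mx <- max(1, max(vapply(stack, max, numeric(1))))
  tiff::writeTIFF(lapply(stack, function(m) m / mx), path)
  invisible(path)
}

#' Write ground truth as plain CSV
#'
#' @param truth Ground-truth tibble.
#' @param path Output file.
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_csv(
    dplyr::select(as_tibble(truth), id = "id", x_nm = "x", y_nm = "y",
                  cluster_id = "cluster_id"), path)
  invisible(path)
}
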