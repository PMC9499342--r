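# Spot detection and sub-pixel localization: band-pass detection with
# connected-component centroids for directly acquired (STED-like) images,
# per-frame Gaussian fitting for blinking (STORM) stacks, multi-emitter
# rejection, temporal grouping and photon-weighted merging.
#
# Image convention: matrices are indexed [row = y, col = x]; the centre of
# pixel (i, j) has coordinates ((j - 0.5) * pixel_size, (i - 0.5) *
# pixel_size) in nm.

# k x k box mean with replicated edges, via an integral image
box_mean <- function(img, k) {
  h <- (k - 1) %/% 2
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[c(rep(1, h), seq_len(nr), rep(nr, h)),
             c(rep(1, h), seq_len(nc), rep(nc, h)), drop = FALSE]
  ii <- apply(apply(pad, 2, cumsum), 1, cumsum) # transposed integral image
  ii <- rbind(0, cbind(0, t(ii)))
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  (ii[r1 + k, c1 + k, drop = FALSE] - ii[r1, c1 + k, drop = FALSE] -
     ii[r1 + k, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]) / (k * k)
}

# direct convolution with a small kernel, replicated edges
conv_small <- function(img, kern) {
  kh <- (nrow(kern) - 1) %/% 2
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[pmin(pmax(seq(1 - kh, nr + kh), 1), nr),
             pmin(pmax(seq(1 - kh, nc + kh), 1), nc), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (di in seq_len(nrow(kern))) {
    for (dj in seq_len(ncol(kern))) {
      if (kern[di, dj] == 0) next
      out <- out + kern[di, dj] *
        pad[(di - 1) + seq_len(nr), (dj - 1) + seq_len(nc), drop = FALSE]
    }
  }
  out
}

# 8-connected component labelling of a logical mask (BFS)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (p in idx) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    queue <- p
    lab[p] <- cur
    while (length(queue) > 0) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- ((q - 1) %% nr) + 1
      j <- ((q - 1) %/% nr) + 1
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        pp <- (jj - 1) * nr + ii
        if (mask[pp] && lab[pp] == 0L) {
          lab[pp] <- cur
          queue <- c(queue, pp)
        }
      }
    }
  }
  lab
}

# TRUE at strict 8-neighbourhood local maxima
local_maxima_8 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- img
  res <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    res <- res & (img > pad[(2:(nr + 1)) + di, (2:(nc + 1)) + dj])
  }
  res
}

# weighted least-squares fit of an integrated rotationally symmetric
# Gaussian inside a window; coordinates in pixel units (centre of pixel
# (i,j) at (j - 0.5, i - 0.5))
fit_integrated_gaussian <- function(win, x0, y0, sigma0) {
  nr <- nrow(win); nc <- ncol(win)
  xe <- 0:nc; ye <- 0:nr
  dat <- as.vector(win)
  w <- 1 / pmax(dat, 1)
  bg0 <- min(win)
  n0 <- max(sum(win - bg0), 1)
  model <- function(p) {
    fx <- diff(stats::pnorm(xe, p[1], exp(p[4])))
    fy <- diff(stats::pnorm(ye, p[2], exp(p[4])))
    p[5] + exp(p[3]) * as.vector(fy %o% fx)
  }
  obj <- function(p) sum(w * (dat - model(p))^2)
  fit <- tryCatch(
    optim(c(x0, y0, log(n0), log(sigma0), bg0), obj, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-9)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  list(x = p[1], y = p[2], photons = exp(p[3]), sigma = exp(p[4]),
       background = p[5], converged = fit$convergence == 0)
}

# least-squares fit of a continuous elliptical Gaussian inside a window
fit_elliptical_gaussian <- function(win, x0, y0, sigma0) {
  nr <- nrow(win); nc <- ncol(win)
  xc <- rep((1:nc) - 0.5, each = nr)
  yc <- rep((1:nr) - 0.5, times = nc)
  dat <- as.vector(win)
  bg0 <- min(win)
  a0 <- max(win) - bg0
  model <- function(p) {
    sx <- exp(p[4]); sy <- exp(p[5]); th <- p[6]
    dx <- xc - p[1]; dy <- yc - p[2]
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    p[7] + exp(p[3]) * exp(-u^2 / (2 * sx^2) - v^2 / (2 * sy^2))
  }
  obj <- function(p) sum((dat - model(p))^2)
  fit <- tryCatch(
    optim(c(x0, y0, log(max(a0, 1e-6)), log(sigma0), log(sigma0), 0, bg0),
          obj, method = "Nelder-Mead",
          control = list(maxit = 4000, reltol = 1e-9)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  sx <- exp(p[4]); sy <- exp(p[5])
  list(x = p[1], y = p[2], sx = sx, sy = sy,
       ellipticity = max(sx, sy) / min(sx, sy),
       converged = fit$convergence == 0)
}

#' Detect spots in a directly acquired (STED-like) image
#'
#' Band-pass filters the image with a difference of box means (3 px minus
#' 5 px kernels), thresholds at `threshold_factor` times the standard
#' deviation of the filtered image, takes 8-connected components, and refines
#' each component's intensity-weighted centroid with a weighted
#' least-squares integrated-Gaussian fit in a 7 px window. Two spots merged
#' into one component yield a single particle at the joint centroid — a
#' known limitation of connected-component detection.
#'
#' @param image Numeric matrix (photon counts).
#' @param pixel_size Pixel size in nm.
#' @param threshold_factor Threshold in units of the filtered image sd
#'   (default 1).
#' @param camera_gain Photons per digital unit.
#' @param fit_window Fit window size in px (default 7).
#' @return Particle tibble: `x`, `y` (nm), `photons`, `frame`, `fit_sigma`
#'   (nm), `ellipticity`.
#' @export
detect_sted_spots <- function(image, pixel_size, threshold_factor = 1,
                              camera_gain = 1, fit_window = 7) {
  stopifnot(is.matrix(image), pixel_size > 0)
  bp <- box_mean(image, 3) - box_mean(image, 5)
  s <- sd(bp)
  if (!is.finite(s) || s == 0) return(empty_particles())
  mask <- bp > threshold_factor * s
  if (!any(mask)) return(empty_particles())
  lab <- label_components(mask)
  bg <- stats::median(image)
  rows <- purrr::map(seq_len(max(lab)), function(k) {
    px <- which(lab == k)
    i <- ((px - 1) %% nrow(image)) + 1
    j <- ((px - 1) %/% nrow(image)) + 1
    wgt <- pmax(image[px] - bg, 0)
    if (sum(wgt) == 0) wgt <- rep(1, length(px))
    cx <- sum((j - 0.5) * wgt) / sum(wgt)
    cy <- sum((i - 0.5) * wgt) / sum(wgt)
    photons <- sum(pmax(image[px] - bg, 0)) / camera_gain
    ref <- refine_in_window(image, cx, cy, fit_window, sigma0 = 1.3)
    tibble(x = ref$x * pixel_size, y = ref$y * pixel_size,
           photons = photons, frame = 1L,
           fit_sigma = ref$sigma * pixel_size,
           ellipticity = 1)
  })
  dplyr::bind_rows(rows)
}

empty_particles <- function() {
  tibble(x = numeric(), y = numeric(), photons = numeric(),
         frame = integer(), fit_sigma = numeric(), ellipticity = numeric())
}

# run the symmetric integrated-Gaussian fit in a window centred on (cx, cy)
# (pixel coordinates); returns global pixel coordinates
refine_in_window <- function(image, cx, cy, fit_window, sigma0) {
  h <- (fit_window - 1) %/% 2
  i0 <- round(cy + 0.5); j0 <- round(cx + 0.5)
  ri <- max(1, i0 - h):min(nrow(image), i0 + h)
  rj <- max(1, j0 - h):min(ncol(image), j0 + h)
  win <- image[ri, rj, drop = FALSE]
  fit <- fit_integrated_gaussian(win, cx - (min(rj) - 1), cy - (min(ri) - 1),
                                 sigma0)
  if (is.null(fit) || !fit$converged) {
    return(list(x = cx, y = cy, sigma = sigma0, photons = NA_real_))
  }
  list(x = fit$x + (min(rj) - 1), y = fit$y + (min(ri) - 1),
       sigma = fit$sigma, photons = fit$photons)
}

#' Localize single emitters in one camera frame
#'
#' The frame is convolved with a zero-integral Gaussian kernel (unit height,
#' width set to the expected PSF), suppressing high-frequency noise and
#' low-frequency background. Peaks are local maxima of the filtered image
#' above `threshold_factor` times its standard deviation. Each peak is fit
#' twice in a square window: first to a continuous elliptical Gaussian
#' (providing the ellipticity used for multi-emitter rejection), then to a
#' rotationally symmetric integrated Gaussian (weighted least squares) which
#' provides the final centre, width and integrated photon count.
#' Non-convergent peaks are dropped and counted in the `dropped` attribute.
#'
#' @param image Numeric matrix (photon counts of one frame).
#' @param psf_sigma Expected PSF sd in nm.
#' @param pixel_size Pixel size in nm.
#' @param threshold_factor Peak threshold in sd units of the filtered frame.
#' @param frame Frame number recorded in the output.
#' @param camera_gain Photons per digital unit.
#' @param fit_window Fit window in px (default 7).
#' @return Particle tibble (`x`, `y` nm, `photons`, `frame`, `fit_sigma` nm,
#'   `ellipticity`) with attribute `dropped`.
#' @export
fit_storm_frame <- function(image, psf_sigma, pixel_size,
                            threshold_factor = 1, frame = 1L,
                            camera_gain = 1, fit_window = 7) {
  stopifnot(is.matrix(image), psf_sigma > 0, pixel_size > 0)
  psf_px <- psf_sigma / pixel_size
  kh <- max(2, ceiling(3 * psf_px))
  d <- (-kh):kh
  g <- exp(-outer(d^2, d^2, "+") / (2 * psf_px^2))
  kern <- g - mean(g) # zero integral, unit height
  filt <- conv_small(image, kern)
  s <- sd(filt)
  if (!is.finite(s) || s == 0) return(structure(empty_particles(), dropped = 0L))
  peaks <- which(local_maxima_8(filt) & filt > threshold_factor * s)
  dropped <- 0L
  rows <- purrr::map(peaks, function(p) {
    i <- ((p - 1) %% nrow(image)) + 1
    j <- ((p - 1) %/% nrow(image)) + 1
    h <- (fit_window - 1) %/% 2
    ri <- max(1, i - h):min(nrow(image), i + h)
    rj <- max(1, j - h):min(ncol(image), j + h)
    win <- image[ri, rj, drop = FALSE] * camera_gain
    ox <- min(rj) - 1; oy <- min(ri) - 1
    ell <- fit_elliptical_gaussian(win, j - 0.5 - ox, i - 0.5 - oy, psf_px)
    sym <- fit_integrated_gaussian(win, j - 0.5 - ox, i - 0.5 - oy, psf_px)
    if (is.null(ell) || is.null(sym) || !sym$converged ||
        sym$x < -1 || sym$x > ncol(win) + 1 ||
        sym$y < -1 || sym$y > nrow(win) + 1 || sym$photons <= 0) {
      dropped <<- dropped + 1L
      return(NULL)
    }
    tibble(x = (sym$x + ox) * pixel_size, y = (sym$y + oy) * pixel_size,
           photons = sym$photons, frame = as.integer(frame),
           fit_sigma = sym$sigma * pixel_size,
           ellipticity = ell$ellipticity)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) out <- empty_particles()
  structure(out, dropped = dropped)
}

#' Localize an entire frame stack
#'
#' Applies [fit_storm_frame()] to every frame of an image stack.
#'
#' @param stack An `nt_image_stack` (or list of matrices).
#' @inheritParams fit_storm_frame
#' @return Particle tibble over all frames with `id` column.
#' @export
fit_storm_stack <- function(stack, psf_sigma, pixel_size = NULL,
                            threshold_factor = 1, camera_gain = 1) {
  pixel_size <- pixel_size %||% attr(stack, "pixel_size")
  out <- purrr::imap(stack, function(img, f) {
    fit_storm_frame(img, psf_sigma, pixel_size, threshold_factor,
                    frame = f, camera_gain = camera_gain)
  }) |> dplyr::bind_rows()
  dplyr::mutate(out, id = dplyr::row_number(), .before = 1)
}

#' Reject multi-emitter peaks
#'
#' Removes peaks likely to stem from several simultaneously active
#' fluorophores fit as one: particles whose ellipticity exceeds
#' `max_ellipticity` or whose fitted width leaves `sigma_range`.
#'
#' @param particles Particle tibble with `ellipticity` and `fit_sigma`.
#' @param max_ellipticity Maximum allowed ellipticity (default 1.3).
#' @param sigma_range Allowed `fit_sigma` range in nm, e.g.
#'   `c(0.5, 2) * psf_sigma`; `NULL` skips the width filter.
#' @return Filtered tibble with attribute `removed` (count).
#' @export
filter_multi_emitter <- function(particles, max_ellipticity = 1.3,
                                 sigma_range = NULL) {
  keep <- particles$ellipticity <= max_ellipticity
  if (!is.null(sigma_range)) {
    keep <- keep & particles$fit_sigma >= sigma_range[1] &
      particles$fit_sigma <= sigma_range[2]
  }
  structure(particles[keep, , drop = FALSE], removed = sum(!keep))
}

#' Group time-contiguous appearances of one emitter
#'
#' Chain-link grouping: a particle joins the group of the nearest particle in
#' the immediately preceding frame lying within `max_displacement_px` pixels;
#' otherwise it starts a new group. A frame gap always breaks the chain.
#'
#' @param particles Particle tibble with `frame`, `x`, `y` (nm).
#' @param pixel_size Pixel size in nm.
#' @param max_displacement_px Maximum linking displacement in pixels
#'   (default 1).
#' @return The tibble, frame-sorted, with a `group` column.
#' @export
group_time_contiguous <- function(particles, pixel_size,
                                  max_displacement_px = 1) {
  stopifnot(all(c("frame", "x", "y") %in% names(particles)))
  p <- dplyr::arrange(as_tibble(particles), .data$frame)
  n <- nrow(p)
  group <- integer(n)
  maxd <- max_displacement_px * pixel_size
  next_group <- 0L
  frames <- p$frame
  for (f in sort(unique(frames))) {
    cur_idx <- which(frames == f)
    prev_idx <- which(frames == f - 1L) # a frame gap breaks every chain
    for (i in cur_idx) {
      g <- 0L
      if (length(prev_idx) > 0) {
        d <- sqrt((p$x[prev_idx] - p$x[i])^2 + (p$y[prev_idx] - p$y[i])^2)
        cand <- which(d <= maxd)
        if (length(cand) > 0) g <- group[prev_idx[cand[which.min(d[cand])]]]
      }
      if (g == 0L) {
        next_group <- next_group + 1L
        g <- next_group
      }
      group[i] <- g
    }
  }
  dplyr::mutate(p, group = group)
}

#' Merge grouped appearances by photon-weighted mean
#'
#' One localization per group: the position is the photon-weighted arithmetic
#' mean of the member positions, photons are summed (total photons are
#' conserved exactly) and the frame is the group's first frame.
#'
#' @param grouped Tibble from [group_time_contiguous()] (needs `group`,
#'   `frame`, `x`, `y`, `photons`).
#' @return Merged localization tibble with `id`, `frame`, `x`, `y`,
#'   `photons`, `n_appearances`.
#' @export
merge_weighted <- function(grouped) {
  stopifnot(all(c("group", "frame", "x", "y", "photons") %in% names(grouped)))
  if (any(!is.finite(grouped$photons)) || any(grouped$photons < 0)) {
    abort("photon weights must be finite and non-negative",
          class = "nt_invalid_parameter")
  }
  totals <- tapply(grouped$photons, grouped$group, sum)
  if (any(totals == 0)) {
    abort("group with zero total photons: weighted mean undefined",
          class = "nt_invalid_parameter")
  }
  out <- grouped |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      x = sum(.data$x * .data$photons) / sum(.data$photons),
      y = sum(.data$y * .data$photons) / sum(.data$photons),
      frame = min(.data$frame),
      n_appearances = dplyr::n(),
      photons = sum(.data$photons),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$frame) |>
    dplyr::select("frame", "x", "y", "photons", "n_appearances")
  dplyr::mutate(out, id = dplyr::row_number(), .before = 1)
}
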