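# ThunderSTORM-dialect localization table I/O and pipeline configuration.

ts_required <- c(frame = "frame", x = "x [nm]", y = "y [nm]",
                 photons = "intensity [photon]")
ts_optional <- c(sigma = "sigma [nm]", uncertainty = "uncertainty [nm]",
                 cluster = "cluster", id = "id")

#' Read a ThunderSTORM-dialect localization table
#'
#' Recognizes the ThunderSTORM CSV header convention: `"frame"`, `"x [nm]"`,
#' `"y [nm]"`, `"intensity [photon]"`, plus optional `"sigma [nm]"`,
#' `"uncertainty [nm]"`, `"id"` and `"cluster"` columns. Row order is
#' preserved; a missing `id` column is filled with the row number.
#'
#' @param path CSV file path.
#' @return A localization tibble with columns `id`, `frame`, `x`, `y`,
#'   `photons` and any optional columns present.
#' @export
read_localizations <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(ts_required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("not a ThunderSTORM localization table: missing column(s) %s",
                  paste0('"', missing, '"', collapse = ", ")),
          class = "nt_format_error")
  }
  out <- tibble(
    frame = as.integer(raw[[ts_required["frame"]]]),
    x = as.numeric(raw[[ts_required["x"]]]),
    y = as.numeric(raw[[ts_required["y"]]]),
    photons = as.numeric(raw[[ts_required["photons"]]])
  )
  for (nm in names(ts_optional)) {
    col <- ts_optional[[nm]]
    if (col %in% names(raw)) out[[nm]] <- raw[[col]]
  }
  bad <- which(!is.finite(out$x) | !is.finite(out$y))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric or missing coordinate at data row %d", bad[1]),
          class = "nt_format_error")
  }
  if (!"id" %in% names(out)) out$id <- seq_len(nrow(out))
  dplyr::relocate(out, "id")
}

#' Write a localization table in ThunderSTORM dialect
#'
#' Emits the bracketed-unit header ThunderSTORM uses; a `cluster` column is
#' appended when cluster labels are present.
#'
#' @param locs Localization tibble (needs `frame`, `x`, `y`, `photons`).
#' @param path Output CSV path.
#' @export
write_localizations <- function(locs, path) {
  stopifnot(all(c("frame", "x", "y", "photons") %in% names(locs)))
  out <- tibble(
    id = locs[["id"]] %||% seq_len(nrow(locs)),
    frame = locs[["frame"]]
  )
  out[["x [nm]"]] <- locs[["x"]]
  out[["y [nm]"]] <- locs[["y"]]
  out[["intensity [photon]"]] <- locs[["photons"]]
  if (!is.null(locs[["sigma"]])) out[["sigma [nm]"]] <- locs[["sigma"]]
  if (!is.null(locs[["uncertainty"]])) {
    out[["uncertainty [nm]"]] <- locs[["uncertainty"]]
  }
  if (!is.null(locs[["cluster"]])) out[["cluster"]] <- locs[["cluster"]]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Validated parameter set for the full analysis pipeline. Defaults follow
#' the published settings for this style of nanocluster analysis: `K = 10`
#' nearest neighbours, minimum cluster size 15, significance `alpha_sig =
#' 0.05` (the maximum probability that a CSR localization is classified as
#' clustered), and 99 CSR simulations for G-function envelopes.
#'
#' @param K Neighbour count of the kNN graph.
#' @param min_cluster_size Minimum localizations per reported nanocluster.
#' @param alpha_sig Significance level for CSR-calibrated noise removal.
#' @param pixel_size Camera pixel size in nm.
#' @param psf_sigma Expected PSF sd in nm.
#' @param photon_thresholds Optional photon thresholds for mesoscale
#'   filtering; `NULL` lets [threshold_scan()] pick quantile-spaced ones.
#' @param csr_simulations CSR patterns for envelope estimation.
#' @param noise_simulations CSR reference graphs for noise classification.
#' @param seed Integer seed for all stochastic stages.
#' @param ... Unknown arguments are an error (typo protection).
#' @return An `nt_config` list.
#' @export
pipeline_config <- function(K = 10, min_cluster_size = 15, alpha_sig = 0.05,
                            pixel_size = 100, psf_sigma = 150,
                            photon_thresholds = NULL,
                            csr_simulations = 99,
                            noise_simulations = 20,
                            seed = 1, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(names(extra), collapse = ", ")),
          class = "nt_invalid_parameter")
  }
  if (K < 1) abort("K must be >= 1", class = "nt_invalid_parameter")
  if (min_cluster_size < 2) abort("min_cluster_size must be >= 2",
                                  class = "nt_invalid_parameter")
  if (!is.finite(alpha_sig) || alpha_sig <= 0 || alpha_sig >= 1) {
    abort("alpha_sig must lie strictly between 0 and 1",
          class = "nt_invalid_parameter")
  }
  if (csr_simulations < 1 || noise_simulations < 1) {
    abort("simulation counts must be >= 1", class = "nt_invalid_parameter")
  }
  structure(list(K = as.integer(K),
                 min_cluster_size = as.integer(min_cluster_size),
                 alpha_sig = alpha_sig, pixel_size = pixel_size,
                 psf_sigma = psf_sigma,
                 photon_thresholds = photon_thresholds,
                 csr_simulations = as.integer(csr_simulations),
                 noise_simulations = as.integer(noise_simulations),
                 seed = as.integer(seed)),
            class = "nt_config")
}

#' @export
print.nt_config <- function(x, ...) {
  cat("<pipeline config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm,
                paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Published STED/STORM comparison medians
#'
#' Median values of the comparative nanoscopy metrics (inter-particle
#' distances, inter-centroid distances) as printed for BTX- and mAb-labelled
#' samples under STORM and STED. These serve as worked-example inputs for
#' [scale_ratio()]; they are shipped as a plain CSV under `extdata`.
#'
#' @return Tibble with columns `metric`, `modality`, `label`, `median`,
#'   `ci_low`, `ci_high`, `units`.
#' @export
published_medians <- function() {
  path <- system.file("extdata", "sted_storm_medians.csv", package = "nanotopo")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
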