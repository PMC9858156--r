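#' Spatial sensitivity map for one source-detector separation
#'
#' Accumulates, for detected packets only, the weight-scaled pathlength
#' spent in each (lateral, depth) bin, and normalizes the map to sum to 1.
#' Trajectories are rotated (ring detector) or mirrored (strip detector) so
#' the exit point lands on the +x axis; the result is the familiar
#' banana-shaped source-detector sampling region.
#'
#' @param model A [skin_model()].
#' @param config A [run_config()].
#' @param sds Source-detector separation in mm.
#' @param lateral_edges Bin edges (mm) along the source-detector axis.
#' @param depth_edges Bin edges (mm) in depth.  Both grids must be uniform.
#' @param detector_width Acceptance width around `sds` (mm).
#' @param lib A [chromophore_library()].
#' @param detector_geometry,bottom_boundary,matched_boundaries As in
#'   [run_transport()].
#' @return An object of class `sensitivity_map`: normalized matrix `map`
#'   (lateral x depth), the bin edges, and the detection count.
#' @export
sensitivity_map <- function(model, config, sds,
                            lateral_edges = seq(-2, sds + 2, by = 0.1),
                            depth_edges = seq(0, sum(vapply(model$layers,
                              `[[`, 0, "thickness")), by = 0.05),
                            detector_width = 0.5,
                            lib = chromophore_library(),
                            detector_geometry = c("ring", "strip"),
                            bottom_boundary = c("transmit", "semi-infinite"),
                            matched_boundaries = FALSE) {
  stopifnot(inherits(model, "skin_model"), inherits(config, "run_config"))
  detector_geometry <- match.arg(detector_geometry)
  bottom_boundary <- match.arg(bottom_boundary)
  if (sds <= 0) stop("sds must be positive", call. = FALSE)
  op <- model_optical_properties(model, config$wavelength, lib)
  lo <- sds - detector_width / 2
  hi <- sds + detector_width / 2
  raw <- .mc_sensitivity(op$thickness, op$mua, op$mus, op$g, op$n,
                         model$n_ambient, c(lo, hi),
                         if (detector_geometry == "ring") 0L else 1L,
                         config$n_photons, config$seed, config$stream,
                         if (config$step_sampling_mode == "total") 0L else 1L,
                         bottom_boundary == "semi-infinite",
                         matched_boundaries, config$roulette,
                         config$roulette_threshold, config$roulette_survival,
                         config$max_path, lo, hi,
                         as.numeric(lateral_edges), as.numeric(depth_edges))
  if (sum(raw$n_detected) < 1)
    stop(sprintf(paste0("insufficient statistics: no packets detected at ",
                        "%g mm (wavelength %g nm)"), sds, config$wavelength),
         call. = FALSE)
  m <- raw$map
  total <- sum(m)
  if (total <= 0)
    stop("insufficient statistics: detected packets left no map deposits",
         call. = FALSE)
  structure(list(map = m / total,
                 lateral_edges = as.numeric(lateral_edges),
                 depth_edges = as.numeric(depth_edges),
                 sds = sds, wavelength = config$wavelength,
                 n_detected = sum(raw$n_detected)),
            class = "sensitivity_map")
}

#' @export
print.sensitivity_map <- function(x, ...) {
  cat(sprintf("<sensitivity_map> %g nm, SDS %g mm, %d detected packets, %d x %d bins\n",
              x$wavelength, x$sds, x$n_detected, nrow(x$map), ncol(x$map)))
  invisible(x)
}

#' Depth of maximum sensitivity
#'
#' Depth (bin centre, mm) at which the laterally integrated sensitivity
#' peaks; a summary of how deep the detected light samples.
#'
#' @param map A `sensitivity_map`.
#' @return Depth in mm.
#' @export
peak_sensitivity_depth <- function(map) {
  stopifnot(inherits(map, "sensitivity_map"))
  prof <- colSums(map$map)
  mid <- (map$depth_edges[-1] + map$depth_edges[-length(map$depth_edges)]) / 2
  mid[which.max(prof)]
}

#' Maximum depth reached by the sensitivity map
#'
#' Deepest bin centre holding at least `frac` of the peak bin value.
#'
#' @param map A `sensitivity_map`.
#' @param frac Fraction of the maximum bin value counting as "reached".
#' @return Depth in mm.
#' @export
sensitivity_reach_depth <- function(map, frac = 1e-3) {
  stopifnot(inherits(map, "sensitivity_map"))
  prof <- colSums(map$map)
  mid <- (map$depth_edges[-1] + map$depth_edges[-length(map$depth_edges)]) / 2
  hit <- which(prof >= frac * max(prof))
  mid[max(hit)]
}

#' Write a sensitivity map as a plain-text matrix
#'
#' Tab-separated matrix with lateral bin centres as rows and depth bin
#' centres as columns, preceded by two header lines carrying the bin
#' centres.
#'
#' @param map A `sensitivity_map`.
#' @param path Output path.
#' @return The map matrix, invisibly.
#' @export
write_sensitivity_map <- function(map, path) {
  stopifnot(inherits(map, "sensitivity_map"))
  xm <- (map$lateral_edges[-1] + map$lateral_edges[-length(map$lateral_edges)]) / 2
  zm <- (map$depth_edges[-1] + map$depth_edges[-length(map$depth_edges)]) / 2
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("# lateral_mm\t", paste(signif(xm, 6), collapse = "\t")),
               paste0("# depth_mm\t", paste(signif(zm, 6), collapse = "\t"))),
             con)
  utils::write.table(map$map, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(map$map)
}
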