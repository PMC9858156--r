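#' Simulation run configuration
#'
#' @param wavelength Source wavelength in nm (library grid point).
#' @param n_photons Photon packet budget, `>= 1`.
#' @param seed Base RNG seed (32-bit integer).
#' @param stream Replicate stream index; `(seed, stream)` pairs give
#'   independent, individually reproducible generators.
#' @param step_sampling_mode `"total"` samples inter-event lengths at the
#'   total interaction rate `mu_t = mu_a + mu_s` (unbiased MCML scheme);
#'   `"scattering"` samples at the scattering rate `mu_s` alone (the literal
#'   free-path density of the source model).  Both deposit
#'   `w * mu_a / (mu_a + mu_s)` per interaction.
#' @param roulette Logical; apply Russian roulette to low-weight packets.
#' @param roulette_threshold Weight below which roulette triggers.
#' @param roulette_survival Survival probability; survivors are reweighted
#'   by `1 / roulette_survival` so expected weight is conserved.
#' @param max_path Safety cap on total pathlength (mm); packets exceeding it
#'   are terminated and booked as truncated.
#' @return An object of class `run_config`.
#' @export
run_config <- function(wavelength, n_photons = 1e5, seed = 1L, stream = 0L,
                       step_sampling_mode = c("total", "scattering"),
                       roulette = TRUE, roulette_threshold = 1e-4,
                       roulette_survival = 0.1, max_path = 1000) {
  step_sampling_mode <- match.arg(step_sampling_mode)
  if (!is.numeric(n_photons) || n_photons < 1)
    stop("n_photons must be at least 1", call. = FALSE)
  if (roulette && (roulette_survival <= 0 || roulette_survival >= 1))
    stop("roulette_survival must lie strictly in (0, 1)", call. = FALSE)
  if (max_path <= 0) stop("max_path must be positive", call. = FALSE)
  structure(list(wavelength = wavelength, n_photons = as.numeric(n_photons),
                 seed = as.integer(seed), stream = as.integer(stream),
                 step_sampling_mode = step_sampling_mode,
                 roulette = roulette,
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 max_path = max_path),
            class = "run_config")
}

#' Sample an exponential free path
#'
#' Inverse-CDF sampling of the inter-event length, `-log(u) / mu`, the
#' exponential deviate with mean `1 / mu`.
#'
#' @param mu Attenuation coefficient in 1/mm, `> 0` (either `mu_s` or
#'   `mu_t = mu_a + mu_s` depending on the step-sampling convention).
#' @param u Uniform deviate in `(0, 1]`.
#' @return Path length in mm.
#' @export
sample_free_path <- function(mu, u) {
  if (any(mu <= 0)) stop("mu must be strictly positive", call. = FALSE)
  if (any(u <= 0 | u > 1)) stop("u must lie in (0, 1]", call. = FALSE)
  -log(u) / mu
}

#' Henyey-Greenstein polar cosine
#'
#' Inverse-CDF sample of the scattering-angle cosine:
#' `(1 + g^2 - ((1 - g^2) / (1 - g + 2 g u))^2) / (2 g)` for `g != 0`,
#' and `2 u - 1` (isotropic) for `g = 0`.
#'
#' @param g Anisotropy factor, `|g| < 1`.
#' @param u Uniform deviate in `[0, 1]`.
#' @return Cosine of the polar scattering angle.
#' @export
hg_cos_theta <- function(g, u) {
  if (abs(g) >= 1) stop("|g| must be < 1", call. = FALSE)
  if (abs(g) < 1e-12) return(2 * u - 1)
  t <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - t^2) / (2 * g)))
}

#' Sample a scattered direction
#'
#' Rotates the incoming unit vector by the Henyey-Greenstein polar angle
#' (from deviate `u1`) and a uniform azimuth `2 pi u2`, in the local frame
#' of the incoming direction.
#'
#' @param g Anisotropy factor, `|g| < 1`.
#' @param u1,u2 Uniform deviates.
#' @param incoming Unit direction vector, length 3.
#' @return New unit direction vector.
#' @export
sample_scatter_direction <- function(g, u1, u2, incoming) {
  if (abs(sum(incoming^2) - 1) > 1e-9)
    stop("incoming direction must be a unit vector", call. = FALSE)
  ct <- hg_cos_theta(g, u1)
  st <- sqrt(max(0, 1 - ct^2))
  phi <- 2 * pi * u2
  ux <- incoming[1]; uy <- incoming[2]; uz <- incoming[3]
  if (abs(uz) > 0.99999) {
    d <- c(st * cos(phi), st * sin(phi), ct * sign(uz))
  } else {
    den <- sqrt(1 - uz^2)
    d <- c(st * (ux * uz * cos(phi) - uy * sin(phi)) / den + ux * ct,
           st * (uy * uz * cos(phi) + ux * sin(phi)) / den + uy * ct,
           -den * st * cos(phi) + uz * ct)
  }
  d / sqrt(sum(d^2))
}

#' Unpolarized Fresnel reflectance
#'
#' @param n1,n2 Refractive indices on the incident and far side.
#' @param cos_i Cosine of the incidence angle (w.r.t. the normal).
#' @return Reflection probability in `[0, 1]`; 1 beyond the critical angle.
#' @export
fresnel_reflectance <- function(n1, n2, cos_i = 1) {
  if (cos_i < 0 || cos_i > 1) stop("cos_i must lie in [0, 1]", call. = FALSE)
  sin_t <- n1 / n2 * sqrt(1 - cos_i^2)
  if (sin_t >= 1) return(1)
  cos_t <- sqrt(1 - sin_t^2)
  rs <- (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t)
  rp <- (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i)
  (rs^2 + rp^2) / 2
}

#' Resolve a boundary crossing
#'
#' Monte Carlo Fresnel test at a planar interface: with probability given by
#' the unpolarized reflectance the packet reflects specularly (z-component
#' negated), otherwise it transmits with the Snell-refracted direction.
#' Beyond the critical angle it always reflects.
#'
#' @param direction Unit direction vector hitting the interface.
#' @param n1,n2 Refractive indices of the incident and far media.
#' @param u Uniform deviate deciding reflection vs transmission.
#' @return List with `action` (`"reflect"` or `"transmit"`) and the new
#'   `direction`.
#' @export
cross_boundary <- function(direction, n1, n2, u) {
  if (abs(sum(direction^2) - 1) > 1e-9)
    stop("direction must be a unit vector", call. = FALSE)
  ci <- abs(direction[3])
  R <- fresnel_reflectance(n1, n2, ci)
  if (u <= R)
    return(list(action = "reflect",
                direction = c(direction[1], direction[2], -direction[3])))
  ratio <- n1 / n2
  sin2 <- ratio^2 * (1 - ci^2)
  ct <- sqrt(max(0, 1 - sin2))
  d <- c(direction[1] * ratio, direction[2] * ratio, sign(direction[3]) * ct)
  list(action = "transmit", direction = d / sqrt(sum(d^2)))
}

#' Launch a batch of photon packets
#'
#' All packets start at the origin heading straight down (+z), with the
#' specular reflection of the normally incident beam at the air-tissue
#' interface already deducted from the initial weight.
#'
#' @param n Number of packets.
#' @param rng_seed Seed for reproducibility (only recorded; launch itself is
#'   deterministic).
#' @param model A [skin_model()]; sets the surface refractive index step.
#' @return An object of class `photon_batch`: matrices `position` (n x 3),
#'   `direction` (n x 3), vector `weight`, matrix `path_by_layer`
#'   (n x layers), logical `alive`.
#' @export
launch <- function(n, rng_seed = 1L, model = build_default_model()) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  r_sp <- fresnel_reflectance(model$n_ambient, model$layers[[1]]$n, 1)
  nl <- length(model$layers)
  structure(list(
    position = matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z"))),
    direction = matrix(rep(c(0, 0, 1), each = n), n, 3,
                       dimnames = list(NULL, c("ux", "uy", "uz"))),
    weight = rep(1 - r_sp, n),
    path_by_layer = matrix(0, n, nl, dimnames = list(NULL, layer_names(model))),
    alive = rep(TRUE, n),
    specular = r_sp, rng_seed = as.integer(rng_seed)),
    class = "photon_batch")
}

#' Deposit absorbed weight at an interaction
#'
#' Each live packet loses the fraction `mua / (mua + mus)` of its weight.
#'
#' @param batch A [launch()]ed `photon_batch`.
#' @param mua,mus Absorption and scattering coefficients (1/mm), `mus > 0`.
#' @return The batch with reduced weights and an `absorbed` attribute
#'   holding the total weight deposited in this call.
#' @export
deposit_absorption <- function(batch, mua, mus) {
  stopifnot(inherits(batch, "photon_batch"))
  if (mua < 0 || mus <= 0)
    stop("need mua >= 0 and mus > 0", call. = FALSE)
  dw <- batch$weight * ifelse(batch$alive, mua / (mua + mus), 0)
  batch$weight <- batch$weight - dw
  attr(batch, "absorbed") <- sum(dw)
  batch
}

#' Russian roulette on low-weight packets
#'
#' Packets below `threshold` survive with probability `survival` and have
#' their weight divided by `survival`; otherwise they are killed.  Expected
#' total weight is conserved.
#'
#' @param batch A `photon_batch`.
#' @param threshold Weight threshold.
#' @param survival Survival probability in `(0, 1)`.
#' @param u Uniform deviates, one per packet (drawn internally if `NULL`).
#' @return Updated batch.
#' @export
roulette <- function(batch, threshold = 1e-4, survival = 0.1, u = NULL) {
  stopifnot(inherits(batch, "photon_batch"))
  if (survival <= 0 || survival >= 1)
    stop("survival must lie strictly in (0, 1)", call. = FALSE)
  n <- length(batch$weight)
  if (is.null(u)) u <- stats::runif(n)
  trig <- batch$alive & batch$weight < threshold
  live <- trig & u <= survival
  dead <- trig & !live
  batch$weight[live] <- batch$weight[live] / survival
  batch$weight[dead] <- 0
  batch$alive[dead] <- FALSE
  batch
}

#' Detector bin edges for a set of source-detector separations
#'
#' Builds a contiguous grid of bins of the given width spanning all
#' requested separations, with every separation sitting at a bin centre.
#'
#' @param sds Source-detector separations in mm.
#' @param width Bin width in mm.
#' @return Numeric vector of bin edges.
#' @export
detector_edges <- function(sds = seq(0.5, 8, by = 0.5), width = 0.5) {
  edges <- seq(min(sds) - width / 2, max(sds) + width / 2, by = width)
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  ok <- vapply(sds, function(d) any(abs(centres - d) < 1e-9), TRUE)
  if (!all(ok))
    stop("every sds must sit at the centre of a bin of the given width",
         call. = FALSE)
  edges
}

#' Run the Monte Carlo transport engine
#'
#' Propagates `config$n_photons` weighted packets through the model at one
#' wavelength and accumulates detected (top-escaping) packets into detector
#' bins, recording weights and total and per-layer pathlengths.
#'
#' @param model A [skin_model()].
#' @param config A [run_config()].
#' @param ring_edges Detector bin edges (mm), e.g. from [detector_edges()].
#' @param lib A [chromophore_library()].
#' @param detector_geometry `"ring"` bins detected packets by exit radius
#'   `sqrt(x^2 + y^2)` (annular detector exploiting radial symmetry);
#'   `"strip"` bins by the exit `|x|` coordinate (the literal Cartesian
#'   reading of a detector placed at `(d, 0, 0)`).
#' @param bottom_boundary `"transmit"` kills packets crossing the bottom of
#'   the last layer (booked as transmitted); `"semi-infinite"` extends the
#'   last layer without bound.
#' @param matched_boundaries Logical; disable all refractive-index steps
#'   (no specular loss, no internal or surface Fresnel events).
#' @param middle_term Epidermis absorption option, see [epidermis_mua()].
#' @return A `detection_ledger`: per-bin accumulators plus run totals.
#' @examples
#' m <- build_default_model(0.02)
#' cfg <- run_config(850, n_photons = 2e4, seed = 7)
#' led <- run_transport(m, cfg, detector_edges(seq(0.5, 4, 0.5)))
#' conservation_residual(led)
#' @export
run_transport <- function(model, config, ring_edges = detector_edges(),
                          lib = chromophore_library(),
                          detector_geometry = c("ring", "strip"),
                          bottom_boundary = c("transmit", "semi-infinite"),
                          matched_boundaries = FALSE,
                          middle_term = c("water", "hbo2")) {
  stopifnot(inherits(model, "skin_model"), inherits(config, "run_config"))
  detector_geometry <- match.arg(detector_geometry)
  bottom_boundary <- match.arg(bottom_boundary)
  middle_term <- match.arg(middle_term)
  if (any(diff(ring_edges) <= 0))
    stop("ring_edges must be strictly increasing", call. = FALSE)
  op <- model_optical_properties(model, config$wavelength, lib, middle_term)
  raw <- .mc_transport(op$thickness, op$mua, op$mus, op$g, op$n,
                       model$n_ambient, as.numeric(ring_edges),
                       if (detector_geometry == "ring") 0L else 1L,
                       config$n_photons, config$seed, config$stream,
                       if (config$step_sampling_mode == "total") 0L else 1L,
                       bottom_boundary == "semi-infinite",
                       matched_boundaries, config$roulette,
                       config$roulette_threshold, config$roulette_survival,
                       config$max_path)
  new_detection_ledger(raw, ring_edges, model, config, detector_geometry,
                       bottom_boundary)
}

new_detection_ledger <- function(raw, ring_edges, model, config,
                                 detector_geometry, bottom_boundary) {
  nm <- layer_names(model)
  dimnames(raw$sum_weighted_path_by_layer) <- list(NULL, nm)
  dimnames(raw$sum_path_by_layer) <- list(NULL, nm)
  structure(c(raw, list(
    ring_edges = as.numeric(ring_edges),
    sds = (ring_edges[-1] + ring_edges[-length(ring_edges)]) / 2,
    layer_names = nm,
    wavelength = config$wavelength,
    detector_geometry = detector_geometry,
    bottom_boundary = bottom_boundary,
    config = config)),
    class = "detection_ledger")
}

#' @export
print.detection_ledger <- function(x, ...) {
  cat(sprintf("<detection_ledger> %g nm, %s detector, %g photons\n",
              x$wavelength, x$detector_geometry, x$launched))
  cat(sprintf("  reflected %.4f  transmitted %.4f  absorbed %.4f  specular %.4f\n",
              x$reflected_weight / x$launched_weight,
              x$transmitted_weight / x$launched_weight,
              x$absorbed_weight / x$launched_weight,
              x$specular_weight / x$launched_weight))
  cat(sprintf("  conservation residual %.2e\n", conservation_residual(x)))
  invisible(x)
}

#' Energy-conservation residual of a completed run
#'
#' Relative difference between launched weight and the sum of all booked
#' channels (specular, top escape, bottom escape, absorption, roulette net
#' loss, safety-cap truncation).  Should be at floating-point level for any
#' completed run.
#'
#' @param ledger A `detection_ledger`.
#' @return Relative residual (dimensionless).
#' @export
conservation_residual <- function(ledger) {
  stopifnot(inherits(ledger, "detection_ledger"))
  booked <- ledger$specular_weight + ledger$reflected_weight +
    ledger$transmitted_weight + ledger$absorbed_weight +
    ledger$truncated_weight + ledger$roulette_killed - ledger$roulette_boost
  abs(ledger$launched_weight - booked) / ledger$launched_weight
}
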