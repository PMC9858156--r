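#' Differential pathlength factor from a detection ledger
#'
#' Mean optical pathlength of the packets detected in the bin containing
#' `sds`, divided by `sds`.  The default estimator weights each packet by
#' its detected weight (consistent with packet splitting); the unweighted
#' estimator averages raw pathlengths over detected packets.
#'
#' @param ledger A `detection_ledger` from [run_transport()].
#' @param sds Source-detector separation in mm; must fall inside a detector
#'   bin with at least one detection.
#' @param estimator `"weighted"` or `"unweighted"`.
#' @return DPF value (dimensionless, `>= 1` for any physical run).
#' @export
dpf_from_ledger <- function(ledger, sds,
                            estimator = c("weighted", "unweighted")) {
  stopifnot(inherits(ledger, "detection_ledger"))
  estimator <- match.arg(estimator)
  k <- findInterval(sds, ledger$ring_edges, rightmost.closed = TRUE)
  if (k < 1 || k > length(ledger$sds))
    stop(sprintf("sds = %g mm lies outside the detector bins", sds),
         call. = FALSE)
  if (ledger$n_detected[k] < 1 || ledger$detected_weight[k] <= 0)
    stop(sprintf(paste0("insufficient statistics: no packets detected in ",
                        "the bin at %g mm (wavelength %g nm)"),
                 sds, ledger$wavelength), call. = FALSE)
  mean_path <- if (estimator == "weighted")
    ledger$sum_weighted_path[k] / ledger$detected_weight[k]
  else
    ledger$sum_path[k] / ledger$n_detected[k]
  mean_path / sds
}

mean_layer_paths <- function(ledger, k, estimator) {
  if (estimator == "weighted")
    ledger$sum_weighted_path_by_layer[k, ] / ledger$detected_weight[k]
  else
    ledger$sum_path_by_layer[k, ] / ledger$n_detected[k]
}

#' Replicate sweep over wavelengths and separations
#'
#' Runs `n_replicates` independently seeded transport simulations per
#' wavelength (one run fills every detector bin simultaneously), and
#' aggregates the DPF mean and across-replicate sample standard deviation
#' for every wavelength x separation cell, together with per-layer mean
#' partial pathlengths.
#'
#' @param model A [skin_model()].
#' @param wavelengths Wavelengths in nm (library grid points).
#' @param sds Source-detector separations in mm (uniform spacing).
#' @param n_photons Photons per replicate.
#' @param n_replicates Number of independently seeded replicates.
#' @param base_seed Base seed; replicate `i` uses stream `i`.
#' @param estimator Passed to [dpf_from_ledger()].
#' @param ring_width Detector bin width in mm.
#' @param ... Further arguments passed to [run_transport()]
#'   (`detector_geometry`, `bottom_boundary`, `lib`, ...).
#' @param config Optional [run_config()] template; its wavelength, seed and
#'   stream fields are overridden per run.
#' @return An object of class `dpf_grid` with matrices `dpf_mean`, `dpf_sd`
#'   (wavelength x separation), array `mean_path_by_layer`
#'   (wavelength x separation x layer), and the replicate-level values in
#'   `dpf_replicates`.
#' @export
replicate_sweep <- function(model, wavelengths = dpf_wavelengths(),
                            sds = seq(0.5, 8, by = 0.5),
                            n_photons = 1e5, n_replicates = 1,
                            base_seed = 1L,
                            estimator = c("weighted", "unweighted"),
                            ring_width = 0.5, ..., config = NULL) {
  stopifnot(inherits(model, "skin_model"))
  estimator <- match.arg(estimator)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  edges <- detector_edges(sds, ring_width)
  nw <- length(wavelengths); ns <- length(sds)
  nl <- length(model$layers)
  reps <- array(NA_real_, c(nw, ns, n_replicates),
                dimnames = list(wavelengths, sds, NULL))
  lay <- array(0, c(nw, ns, nl),
               dimnames = list(wavelengths, sds, layer_names(model)))
  for (iw in seq_len(nw)) {
    lay_acc <- matrix(0, ns, nl)
    for (r in seq_len(n_replicates)) {
      cfg <- if (is.null(config))
        run_config(wavelengths[iw], n_photons = n_photons,
                   seed = base_seed, stream = r)
      else {
        config$wavelength <- wavelengths[iw]
        config$n_photons <- n_photons
        config$seed <- as.integer(base_seed)
        config$stream <- as.integer(r)
        config
      }
      led <- run_transport(model, cfg, edges, ...)
      for (is in seq_len(ns)) {
        val <- tryCatch(dpf_from_ledger(led, sds[is], estimator),
                        error = function(e)
                          stop(sprintf(
                            "replicate %d, wavelength %g nm: %s",
                            r, wavelengths[iw], conditionMessage(e)),
                            call. = FALSE))
        reps[iw, is, r] <- val
        k <- findInterval(sds[is], led$ring_edges, rightmost.closed = TRUE)
        lay_acc[is, ] <- lay_acc[is, ] +
          mean_layer_paths(led, k, estimator) / n_replicates
      }
    }
    lay[iw, , ] <- lay_acc
  }
  dpf_mean <- apply(reps, c(1, 2), mean)
  dpf_sd <- if (n_replicates > 1) apply(reps, c(1, 2), stats::sd)
            else matrix(0, nw, ns, dimnames = dimnames(dpf_mean))
  structure(list(wavelengths = as.numeric(wavelengths),
                 sds = as.numeric(sds),
                 dpf_mean = dpf_mean, dpf_sd = dpf_sd,
                 n_replicates = as.integer(n_replicates),
                 sd_degenerate = n_replicates == 1,
                 mean_path_by_layer = lay,
                 dpf_replicates = reps,
                 estimator = estimator,
                 n_photons = n_photons, base_seed = as.integer(base_seed)),
            class = "dpf_grid")
}

#' @export
print.dpf_grid <- function(x, ...) {
  cat(sprintf("<dpf_grid> %d wavelengths x %d separations, %d replicate(s)%s\n",
              length(x$wavelengths), length(x$sds), x$n_replicates,
              if (x$sd_degenerate) " [SD degenerate: single replicate]" else ""))
  print(round(t(x$dpf_mean), 3))
  invisible(x)
}

#' Modified Beer-Lambert attenuation
#'
#' Attenuation of light by an absorber in a scattering medium,
#' `A = epsilon * C * d * DPF`: the product of molar absorption
#' coefficient, concentration, source-detector separation and differential
#' pathlength factor.
#'
#' @param epsilon Molar absorption coefficient.
#' @param concentration Chromophore concentration.
#' @param d Source-detector separation (mm).
#' @param dpf Differential pathlength factor.
#' @return Attenuation (dimensionless when units of `epsilon` and
#'   `concentration` are consistent).
#' @export
mbll_attenuation <- function(epsilon, concentration, d, dpf) {
  if (any(c(epsilon, concentration, d, dpf) < 0))
    stop("all inputs must be non-negative", call. = FALSE)
  epsilon * concentration * d * dpf
}

#' Write a DPF grid in the wide table dialect
#'
#' Rows are source-detector separations, columns `DPF<wavelength>nm`.
#'
#' @param grid A `dpf_grid`.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_dpf_csv <- function(grid, path) {
  stopifnot(inherits(grid, "dpf_grid"))
  df <- data.frame(sds_mm = grid$sds,
                   t(grid$dpf_mean), check.names = FALSE)
  names(df) <- c("SDS_mm", sprintf("DPF%gnm", grid$wavelengths))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Write a DPF grid in long format with replicate spread
#'
#' @param grid A `dpf_grid`.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_dpf_long_csv <- function(grid, path) {
  stopifnot(inherits(grid, "dpf_grid"))
  df <- expand.grid(sds_mm = grid$sds, wavelength_nm = grid$wavelengths,
                    KEEP.OUT.ATTRS = FALSE)
  df$dpf_mean <- as.vector(t(grid$dpf_mean))
  df$dpf_sd <- as.vector(t(grid$dpf_sd))
  df$n_replicates <- grid$n_replicates
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Write per-layer mean partial pathlengths
#'
#' Long format: wavelength, separation, layer, mean partial pathlength (mm).
#'
#' @param grid A `dpf_grid`.
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_layer_path_csv <- function(grid, path) {
  stopifnot(inherits(grid, "dpf_grid"))
  dn <- dimnames(grid$mean_path_by_layer)
  df <- expand.grid(wavelength_nm = as.numeric(dn[[1]]),
                    sds_mm = as.numeric(dn[[2]]),
                    layer = dn[[3]],
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$mean_path_mm <- as.vector(grid$mean_path_by_layer)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
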