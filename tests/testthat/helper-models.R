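# Shared fixtures: small models and the replication sweep protocol.

# two-layer toy used for oracle-equivalence checks: modest scattering so the
# pure-R walker stays fast
toy_two_layer <- function() {
  slab_model(mua = c(0.05, 0.02), mus = c(2, 1), thickness = c(1, 3), g = 0)
}

# weighted mean detected path of the engine in one detector bin
engine_mean_path <- function(model, cfg, edges, lib, k = 1) {
  led <- run_transport(model, cfg, edges, lib = lib)
  led$sum_weighted_path[k] / led$detected_weight[k]
}

# The replication protocol for the default skin model: one sweep per
# wavelength with the production geometry (strip detection, semi-infinite
# subcutis, weighted estimator).  Short wavelengths (<= 550 nm) are run
# without roulette under a 150 mm path cap so that every detector bin
# receives detections: hemoglobin absorption there is so strong that
# weight-based termination would empty the far bins at any photon budget,
# while the discarded deep paths carry weights far below any contribution
# to the weighted estimator.
replication_grid <- function(melanin = 0.02, wavelengths = dpf_wavelengths(),
                             sds = seq(0.5, 8, 0.5), n_photons = 3e5,
                             n_replicates = 2, base_seed = 20260923) {
  model <- build_default_model(melanin)
  grids <- lapply(wavelengths, function(wl) {
    cfg <- if (wl <= 550)
      run_config(wl, roulette = FALSE, max_path = 150)
    else run_config(wl)
    replicate_sweep(model, wl, sds, n_photons = n_photons,
                    n_replicates = n_replicates, base_seed = base_seed,
                    config = cfg, detector_geometry = "strip",
                    bottom_boundary = "semi-infinite")
  })
  list(
    wavelengths = wavelengths, sds = sds,
    dpf_mean = do.call(rbind, lapply(grids, function(g) g$dpf_mean)),
    dpf_sd = do.call(rbind, lapply(grids, function(g) g$dpf_sd)),
    grids = grids
  )
}

# published DPF table being replicated (rows: SDS 0.5-8 mm step 0.5;
# columns: 450-1050 nm step 100)
published_dpf <- function() {
  m <- matrix(c(
    9.327229, 7.613623, 7.734551, 8.445864, 8.731699, 9.321385, 9.629079,
    14.26636, 9.017028, 6.849151, 6.742956, 6.827569, 7.24332, 7.628147,
    18.92219, 10.79773, 6.926007, 6.171503, 6.097595, 6.192436, 6.473498,
    23.20217, 12.52319, 7.222662, 5.991458, 5.791009, 5.613065, 5.772583,
    26.85853, 14.18709, 7.579191, 5.985923, 5.645795, 5.265959, 5.288481,
    30.09627, 15.64019, 7.971814, 6.028839, 5.61251, 5.041451, 4.947292,
    32.83371, 16.98709, 8.331424, 6.102681, 5.596167, 4.896995, 4.705665,
    35.20655, 18.15731, 8.667086, 6.193406, 5.623161, 4.793538, 4.519836,
    37.30747, 19.13173, 9.021267, 6.297507, 5.662255, 4.73143, 4.384798,
    39.06324, 20.0042, 9.277562, 6.376903, 5.692662, 4.65514, 4.272771,
    40.29488, 20.77222, 9.541198, 6.439553, 5.731603, 4.625515, 4.171025,
    41.39538, 21.38013, 9.748879, 6.525236, 5.773241, 4.581958, 4.096541,
    42.31183, 22.13103, 9.885177, 6.558909, 5.777782, 4.535969, 4.004704,
    43.00748, 22.39849, 10.01952, 6.623501, 5.797535, 4.50906, 3.953183,
    43.06239, 22.64816, 10.16962, 6.62868, 5.828102, 4.474714, 3.897391,
    43.21896, 22.80911, 10.2432, 6.636324, 5.813229, 4.445111, 3.844256),
    nrow = 16, byrow = TRUE)
  dimnames(m) <- list(seq(0.5, 8, 0.5), seq(450, 1050, 100))
  m
}
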