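test_that("every booked energy channel balances the launched weight", {
  m <- build_default_model(0.02)
  edges <- detector_edges(seq(0.5, 4, 0.5))
  configs <- list(
    list(cfg = run_config(850, n_photons = 2e4, seed = 1)),
    list(cfg = run_config(850, n_photons = 2e4, seed = 2),
         matched_boundaries = TRUE),
    list(cfg = run_config(1050, n_photons = 2e4, seed = 3),
         bottom_boundary = "semi-infinite"),
    list(cfg = run_config(650, n_photons = 2e4, seed = 4,
                          step_sampling_mode = "scattering")),
    list(cfg = run_config(450, n_photons = 2e4, seed = 5,
                          roulette = FALSE, max_path = 100),
         detector_geometry = "strip")
  )
  for (cc in configs) {
    led <- do.call(run_transport,
                   c(list(model = m, config = cc$cfg, ring_edges = edges),
                     cc[names(cc) != "cfg"]))
    expect_lt(conservation_residual(led), 1e-6)
    expect_true(all(led$detected_weight >= 0))
    expect_true(all(led$n_detected >= 0))
  }
})

test_that("runs are bit-identical under the same seed and stream", {
  m <- build_default_model(0.02)
  cfg <- run_config(850, n_photons = 1e4, seed = 99, stream = 4)
  a <- run_transport(m, cfg, detector_edges(seq(0.5, 3, 0.5)))
  b <- run_transport(m, cfg, detector_edges(seq(0.5, 3, 0.5)))
  for (f in c("detected_weight", "sum_weighted_path", "absorbed_weight",
              "reflected_weight", "transmitted_weight", "n_detected"))
    expect_identical(a[[f]], b[[f]])
  cfg2 <- run_config(850, n_photons = 1e4, seed = 99, stream = 5)
  c <- run_transport(m, cfg2, detector_edges(seq(0.5, 3, 0.5)))
  expect_false(identical(a$detected_weight, c$detected_weight))
})

test_that("per-layer pathlengths decompose the total path exactly", {
  m <- build_default_model(0.02)
  led <- run_transport(m, run_config(850, n_photons = 3e4, seed = 7),
                       detector_edges(seq(0.5, 4, 0.5)))
  expect_equal(unname(rowSums(led$sum_weighted_path_by_layer)),
               led$sum_weighted_path, tolerance = 1e-9)
  expect_equal(unname(rowSums(led$sum_path_by_layer)),
               led$sum_path, tolerance = 1e-9)
  expect_true(all(led$sum_path_by_layer >= 0))
})

test_that("detected paths always exceed the geometric separation", {
  m <- build_default_model(0.02)
  led <- run_transport(m, run_config(850, n_photons = 5e4, seed = 8),
                       detector_edges(seq(0.5, 4, 0.5)))
  for (d in led$sds[led$n_detected > 0]) {
    expect_gte(dpf_from_ledger(led, d), 1)
    expect_gte(dpf_from_ledger(led, d, estimator = "unweighted"), 1)
  }
})

test_that("a non-scattering slab transmits the Beer-Lambert fraction", {
  mua <- 0.5; L <- 2
  slab <- slab_model(mua = mua, mus = 0, thickness = L)
  n <- 4e4
  led <- run_transport(slab$model, run_config(650, n_photons = n, seed = 21),
                       ring_edges = c(0, 1), lib = slab$lib,
                       matched_boundaries = TRUE)
  p <- exp(-mua * L)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(led$transmitted_weight / led$launched_weight - p), 3 * se)
})

test_that("a nearly conservative scattering half-space reflects almost all light", {
  hs <- slab_model(mua = 0.001, mus = 10, thickness = 200, g = 0.9)
  led <- run_transport(hs$model,
                       run_config(650, n_photons = 5e3, seed = 22,
                                  max_path = 5000),
                       ring_edges = c(0, 50), lib = hs$lib,
                       matched_boundaries = TRUE)
  expect_gt(led$reflected_weight / led$launched_weight, 0.9)
})

test_that("empty detector bins raise an insufficient-statistics error", {
  m <- build_default_model(0.02)
  led <- run_transport(m, run_config(450, n_photons = 100, seed = 1),
                       detector_edges())
  expect_error(dpf_from_ledger(led, 8), "insufficient statistics")
  expect_error(dpf_from_ledger(led, 25), "outside the detector bins")
})

test_that("engine inputs are validated", {
  m <- build_default_model(0.02)
  expect_error(run_config(850, n_photons = 0), "at least 1")
  expect_error(run_config(850, roulette_survival = 1.5), "strictly in")
  expect_error(run_transport(m, run_config(850, n_photons = 10),
                             ring_edges = c(1, 1)), "strictly increasing")
  expect_error(run_transport(m, run_config(700, n_photons = 10)),
               "not on the model grid")
})
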