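# a hand-built ledger with prescribed detections, for estimator arithmetic
fake_ledger <- function(edges, n, w, wp, p) {
  structure(list(ring_edges = edges,
                 sds = (edges[-1] + edges[-length(edges)]) / 2,
                 n_detected = n, detected_weight = w,
                 sum_weighted_path = wp, sum_path = p,
                 wavelength = 650),
            class = "detection_ledger")
}

test_that("the DPF estimator divides mean detected path by separation", {
  # one packet, path 10 mm, detector at 2 mm
  led <- fake_ledger(c(1.5, 2.5), n = 1, w = 1, wp = 10, p = 10)
  expect_equal(dpf_from_ledger(led, 2), 5)
  # two unit-weight packets with paths 4 and 6 mm
  led <- fake_ledger(c(1.5, 2.5), n = 2, w = 2, wp = 10, p = 10)
  expect_equal(dpf_from_ledger(led, 2), 2.5)
  expect_equal(dpf_from_ledger(led, 2, "unweighted"), 2.5)
  # unequal weights 1 and 3: weighted and unweighted estimators separate
  led <- fake_ledger(c(1.5, 2.5), n = 2, w = 4, wp = 1 * 4 + 3 * 6, p = 10)
  expect_equal(dpf_from_ledger(led, 2), 2.75)
  expect_equal(dpf_from_ledger(led, 2, "unweighted"), 2.5)
  expect_error(dpf_from_ledger(fake_ledger(c(1.5, 2.5), 0, 0, 0, 0), 2),
               "insufficient statistics")
})

test_that("modified Beer-Lambert attenuation is the printed product", {
  expect_equal(mbll_attenuation(1, 1, 2, 5), 10)
  expect_equal(mbll_attenuation(0, 1, 2, 5), 0)
  expect_equal(mbll_attenuation(0.3, 2, 4, 10), 0.3 * 2 * 4 * 10)
  expect_equal(mbll_attenuation(1, 1, 2, 10), 2 * mbll_attenuation(1, 1, 2, 5))
  expect_error(mbll_attenuation(-1, 1, 1, 1), "non-negative")
})

test_that("replicate sweeps aggregate means, spreads and layer paths", {
  m <- build_default_model(0.02)
  sds <- seq(0.5, 2, 0.5)
  g <- replicate_sweep(m, 850, sds, n_photons = 2e4, n_replicates = 4,
                       base_seed = 5)
  expect_equal(dim(g$dpf_mean), c(1, 4))
  expect_true(all(g$dpf_mean >= 1))
  expect_true(all(g$dpf_sd >= 0))
  expect_false(g$sd_degenerate)
  # replicate values are genuinely independent draws
  expect_gt(max(g$dpf_sd), 0)
  # per-layer mean paths sum to the total mean path (= DPF x separation),
  # averaged over replicates: exact bookkeeping identity per replicate
  g1 <- replicate_sweep(m, 850, sds, n_photons = 2e4, n_replicates = 1,
                        base_seed = 5)
  totals <- apply(g1$mean_path_by_layer[1, , ], 1, sum)
  expect_equal(unname(totals), unname(g1$dpf_mean[1, ] * sds),
               tolerance = 1e-9)
  # single replicate: SD is zero by convention and flagged
  expect_true(g1$sd_degenerate)
  expect_true(all(g1$dpf_sd == 0))
})

test_that("replicate spread shrinks with photon budget and grows with separation", {
  m <- build_default_model(0.02)
  # Monte Carlo error scales as 1/sqrt(n): an order of magnitude more
  # photons should shrink the replicate SD by about sqrt(10)
  # 24 replicates keep the chi-square noise of each SD estimate well below
  # the expected sqrt(10) separation
  g_small <- replicate_sweep(m, 1050, 1, n_photons = 2e3, n_replicates = 24,
                             base_seed = 31, detector_geometry = "strip",
                             bottom_boundary = "semi-infinite")
  g_big <- replicate_sweep(m, 1050, 1, n_photons = 2e4, n_replicates = 24,
                           base_seed = 32, detector_geometry = "strip",
                           bottom_boundary = "semi-infinite")
  expect_gt(g_small$dpf_sd[1, 1], g_big$dpf_sd[1, 1])
  ratio <- g_small$dpf_sd[1, 1] / g_big$dpf_sd[1, 1]
  expect_gt(ratio, sqrt(10) / 1.8)
  expect_lt(ratio, sqrt(10) * 1.8)
  # farther detectors collect fewer, more variable paths: the replicate
  # spread of the mean detected pathlength grows with separation
  g_sds <- replicate_sweep(m, 1050, c(1, 6), n_photons = 2e4,
                           n_replicates = 12, base_seed = 33,
                           detector_geometry = "strip",
                           bottom_boundary = "semi-infinite")
  path_sd <- apply(g_sds$dpf_replicates[1, , ] * c(1, 6), 1, sd)
  expect_gt(path_sd[2], path_sd[1])
})

test_that("sweep errors carry wavelength and replicate context", {
  m <- build_default_model(0.02)
  expect_error(
    replicate_sweep(m, 450, seq(0.5, 8, 0.5), n_photons = 200,
                    n_replicates = 1, base_seed = 1),
    "replicate 1, wavelength 450")
})

test_that("grid writers produce the wide table dialect and long formats", {
  m <- build_default_model(0.02)
  g <- replicate_sweep(m, c(850, 1050), seq(0.5, 1.5, 0.5), n_photons = 1e4,
                       n_replicates = 2, base_seed = 6)
  tmp <- tempfile(fileext = ".csv")
  wide <- write_dpf_csv(g, tmp)
  expect_equal(names(wide), c("SDS_mm", "DPF850nm", "DPF1050nm"))
  back <- read.csv(tmp, check.names = FALSE)
  expect_equal(back$SDS_mm, c(0.5, 1, 1.5))
  expect_equal(back$DPF850nm, unname(g$dpf_mean[1, ]), tolerance = 1e-6)
  lng <- write_dpf_long_csv(g, tmp)
  expect_equal(nrow(lng), 6)
  expect_true(all(c("dpf_mean", "dpf_sd", "n_replicates") %in% names(lng)))
  lp <- write_layer_path_csv(g, tmp)
  expect_equal(nrow(lp), 2 * 3 * 7)
  expect_true(all(lp$mean_path_mm >= 0))
})
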