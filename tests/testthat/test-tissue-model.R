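test_that("melanin absorption follows the packaged power law", {
  # direct scalar evaluation of the law, written out independently
  expect_equal(melanin_mua(450), 6.6e10 * 450^(-3.33))
  expect_equal(melanin_mua(450), 96.54, tolerance = 1e-2)
  # doubling the wavelength scales by 2^-3.33 for any lambda in range
  for (wl in c(450, 500, 525)) {
    expect_equal(melanin_mua(2 * wl) / melanin_mua(wl), 2^(-3.33),
                 tolerance = 1e-12)
  }
  expect_true(melanin_mua(1050) < melanin_mua(450))
  expect_true(all(diff(melanin_mua(dpf_wavelengths())) < 0))
  # constant is configurable
  expect_equal(melanin_mua(450, c_mel = 6.6e11), 10 * melanin_mua(450))
  expect_error(melanin_mua(449), "450-1050")
  expect_error(melanin_mua(1100), "450-1050")
})

test_that("epidermis mixture reduces correctly at the degenerate corners", {
  lib <- chromophore_library()
  for (wl in c(450, 750, 1050)) {
    row <- lib[lib$wavelength == wl, ]
    expect_equal(epidermis_mua(wl, 0, 0, lib), row$mua_other)
    expect_equal(epidermis_mua(wl, 1, 0, lib), melanin_mua(wl))
    expect_equal(epidermis_mua(wl, 0, 1, lib), row$mua_water)
  }
  # mixture is strictly increasing in the melanin fraction when melanin
  # absorbs more than the baseline (true at every grid wavelength)
  v <- vapply(c(0.02, 0.1, 0.2), function(vm)
    epidermis_mua(550, vm, 0.2, lib), 0)
  expect_true(all(diff(v) > 0))
  # hand-computed mixture, 20% melanin, 20% water at 650 nm
  row650 <- lib[lib$wavelength == 650, ]
  expect_equal(epidermis_mua(650, 0.2, 0.2, lib),
               0.2 * melanin_mua(650) + 0.2 * row650$mua_water +
                 0.6 * row650$mua_other)
  expect_error(epidermis_mua(650, -0.1, 0.2, lib), "v_mel")
  expect_error(epidermis_mua(650, 0.6, 0.6, lib), "exceed 1")
})

test_that("the printed-mixture switch pairs the water fraction with HbO2", {
  lib <- chromophore_library()
  row <- lib[lib$wavelength == 850, ]
  expect_equal(epidermis_mua(850, 0.02, 0.2, lib, middle_term = "hbo2"),
               0.02 * melanin_mua(850) + 0.2 * row$mua_hbo2 +
                 0.78 * row$mua_other)
  # the two readings genuinely differ wherever water and HbO2 differ
  expect_false(isTRUE(all.equal(
    epidermis_mua(850, 0.02, 0.2, lib),
    epidermis_mua(850, 0.02, 0.2, lib, middle_term = "hbo2"))))
})

test_that("layer absorption blends chromophores by volume fraction", {
  lib <- chromophore_library()
  sc <- layer_spec("stratum_corneum", 0.02, mus = rep(60, 7),
                   v_blood = 0, v_water = 0.05)
  for (wl in dpf_wavelengths()) {
    row <- lib[lib$wavelength == wl, ]
    expect_equal(layer_mua(sc, wl, lib),
                 0.05 * row$mua_water + 0.95 * row$mua_other)
  }
  # plain layer with no chromophores reduces to the baseline
  bare <- layer_spec("bare", 1, mus = rep(10, 7))
  expect_equal(layer_mua(bare, 650, lib),
               lib$mua_other[lib$wavelength == 650])
  # deep blood net dermis absorbs more than reticular dermis at 550 nm,
  # where blood dominates the baseline
  deep <- layer_spec("deep", 0.3, rep(10, 7), v_blood = 0.1, v_water = 0.7)
  ret <- layer_spec("ret", 0.2, rep(10, 7), v_blood = 0.04, v_water = 0.7)
  expect_gt(layer_mua(deep, 550, lib), layer_mua(ret, 550, lib))
  # melanin-bearing layers dispatch to the epidermis mixture
  epi <- layer_spec("epi", 0.25, rep(10, 7), v_water = 0.2, v_mel = 0.02)
  expect_equal(layer_mua(epi, 550, lib), epidermis_mua(550, 0.02, 0.2, lib))
})

test_that("layer absorption is linear in each volume fraction", {
  lib <- chromophore_library()
  f <- function(vb) layer_mua(
    layer_spec("x", 1, rep(10, 7), v_blood = vb, v_water = 0.3), 750, lib)
  # second finite difference of a linear function vanishes
  expect_equal(f(0.3) - 2 * f(0.2) + f(0.1), 0, tolerance = 1e-12)
  g <- function(vw) layer_mua(
    layer_spec("x", 1, rep(10, 7), v_blood = 0.1, v_water = vw), 950, lib)
  expect_equal(g(0.6) - 2 * g(0.4) + g(0.2), 0, tolerance = 1e-12)
  # mixture weights always total one: scaling all chromophores by a
  # constant scales the result by the same constant
  lib2 <- chromophore_library(
    mua_water = 2 * lib$mua_water, mua_hb = 2 * lib$mua_hb,
    mua_hbo2 = 2 * lib$mua_hbo2, mua_other = 2 * lib$mua_other)
  ly <- layer_spec("x", 1, rep(10, 7), v_blood = 0.2, v_water = 0.5)
  expect_equal(layer_mua(ly, 850, lib2), 2 * layer_mua(ly, 850, lib))
})

test_that("the default model reproduces the packaged seven-layer stack", {
  m <- build_default_model(0.02)
  expect_length(m$layers, 7)
  expect_identical(layer_names(m)[2], "epidermis")
  th <- vapply(m$layers, `[[`, 0, "thickness")
  expect_equal(th, c(0.02, 0.25, 0.1, 0.08, 0.2, 0.3, 2))
  expect_equal(sum(th), 2.95)
  expect_equal(m$layers[[2]]$v_mel, 0.02)
  expect_equal(m$layers[[1]]$mus,
               c(60.61, 41.74, 22.33, 15.05, 13.32, 9.5, 7.52))
  expect_equal(layer_depths(m), cumsum(c(0, th)))
  # melanin-free epidermis reduces to the water/baseline mixture
  m0 <- build_default_model(0)
  lib <- chromophore_library()
  row <- lib[lib$wavelength == 650, ]
  expect_equal(layer_mua(m0$layers[[2]], 650, lib),
               0.2 * row$mua_water + 0.8 * row$mua_other)
  # optical property table: positive scattering, non-negative absorption
  for (wl in dpf_wavelengths()) {
    op <- model_optical_properties(m, wl)
    expect_true(all(op$mua >= 0))
    expect_true(all(op$mus > 0))
  }
  expect_error(model_optical_properties(m, 700), "not on the model grid")
})

test_that("chromophore library enforces its invariants", {
  lib <- chromophore_library()
  expect_equal(range(lib$wavelength), c(450, 1050))
  expect_true(all(as.matrix(lib[-1]) >= 0))
  expect_error(chromophore_library(c(500, 600)), "custom grid")
  expect_error(chromophore_library(mua_water = rep(-1, 7)), "non-negative")
  custom <- chromophore_library(c(500, 600), mua_water = c(1, 2),
                                mua_hb = c(0, 0), mua_hbo2 = c(0, 0),
                                mua_other = c(0.1, 0.1))
  expect_equal(custom$mua_water, c(1, 2))
})
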