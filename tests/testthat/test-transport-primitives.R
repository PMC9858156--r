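test_that("free-path sampling inverts the exponential law", {
  expect_equal(sample_free_path(5, 1), 0)
  expect_equal(sample_free_path(2, exp(-1)), 0.5)
  set.seed(11)
  mu <- 22.33   # default-stack scattering coefficient at 650 nm
  x <- sample_free_path(mu, runif(2e5))
  se <- (1 / mu) / sqrt(length(x))   # exponential: sd equals the mean
  expect_lt(abs(mean(x) - 1 / mu), 3 * se)
  expect_error(sample_free_path(0, 0.5), "strictly positive")
  expect_error(sample_free_path(-1, 0.5), "strictly positive")
  expect_error(sample_free_path(2, 0), "\\(0, 1\\]")
})

test_that("Henyey-Greenstein sampling reproduces the mean cosine", {
  set.seed(12)
  for (g in c(0, 0.5, 0.9)) {
    draws <- hg_cos_theta(g, runif(2e5))
    se <- sd(draws) / sqrt(length(draws))
    # quadrature of the HG density is the independent reference
    expect_lt(abs(mean(draws) - hg_mean_cos_numeric(g)), 3 * se)
    expect_true(all(draws >= -1 & draws <= 1))
  }
  expect_error(hg_cos_theta(1, 0.5), "< 1")
  expect_error(hg_mean_cos_numeric(-1), "< 1")
})

test_that("scattered directions stay unit vectors in every frame", {
  set.seed(13)
  for (i in 1:50) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    d <- sample_scatter_direction(runif(1, -0.9, 0.95), runif(1), runif(1), v)
    expect_equal(sum(d^2), 1, tolerance = 1e-9)
  }
  # near-vertical incoming directions use the degenerate-frame branch
  d <- sample_scatter_direction(0.9, 0.3, 0.7, c(0, 0, 1))
  expect_equal(sum(d^2), 1, tolerance = 1e-9)
  expect_error(sample_scatter_direction(0.9, 0.3, 0.7, c(0, 0, 2)),
               "unit vector")
})

test_that("Fresnel boundaries reflect and refract correctly", {
  expect_equal(fresnel_reflectance(1.37, 1.37, 1), 0)
  expect_equal(fresnel_reflectance(1.37, 1.0, 1), ((1.37 - 1) / (1.37 + 1))^2)
  # beyond the critical angle everything reflects
  cos_crit <- sqrt(1 - (1 / 1.37)^2)
  expect_equal(fresnel_reflectance(1.37, 1.0, cos_crit * 0.9), 1)
  # matched interface transmits with probability one, direction unchanged
  v <- c(0.6, 0, 0.8)
  out <- cross_boundary(v, 1.4, 1.4, u = 0.999999)
  expect_identical(out$action, "transmit")
  expect_equal(out$direction, v)
  # reflection flips the z-component
  out <- cross_boundary(v, 1.37, 1.0, u = 0)
  expect_identical(out$action, "reflect")
  expect_equal(out$direction, c(0.6, 0, -0.8))
  # Snell refraction preserves n sin(theta)
  out <- cross_boundary(v, 1.37, 1.0, u = 1)
  expect_identical(out$action, "transmit")
  sin_i <- sqrt(1 - v[3]^2); sin_t <- sqrt(1 - out$direction[3]^2)
  expect_equal(1.37 * sin_i, 1.0 * sin_t, tolerance = 1e-12)
})

test_that("launch produces a pencil beam with the specular loss deducted", {
  m <- build_default_model(0.02)
  b <- launch(5, rng_seed = 3, model = m)
  expect_length(b$weight, 5)
  r_sp <- ((1.37 - 1) / (1.37 + 1))^2
  expect_equal(b$weight, rep(1 - r_sp, 5))
  expect_equal(unname(b$direction[1, ]), c(0, 0, 1))
  expect_true(all(b$position == 0))
  expect_true(all(b$path_by_layer == 0))
  # two launches with identical seeds agree
  expect_identical(b, launch(5, rng_seed = 3, model = m))
  # matched ambient medium: no specular loss
  mm <- build_default_model(0.02, n = 1.0)
  expect_equal(launch(3, model = mm)$weight, rep(1, 3))
})

test_that("absorption deposit and roulette conserve expected weight", {
  m <- build_default_model(0.02)
  b <- launch(100, model = m)
  w0 <- sum(b$weight)
  expect_equal(deposit_absorption(b, 0, 10)$weight, b$weight)
  b2 <- deposit_absorption(b, 2, 2)
  expect_equal(b2$weight, b$weight / 2)
  expect_equal(attr(b2, "absorbed"), w0 / 2)
  # roulette: untouched above threshold, reweighted below
  b$weight[] <- 1e-5
  out <- roulette(b, threshold = 1e-4, survival = 0.1,
                  u = rep(c(0.05, 0.5), 50))
  expect_equal(out$weight[out$alive], rep(1e-4, sum(out$alive)))
  expect_equal(out$weight[!out$alive], rep(0, sum(!out$alive)))
  # expectation test over many packets
  set.seed(14)
  big <- launch(2e4, model = m)
  big$weight[] <- 1e-5
  pre <- sum(big$weight)
  post <- sum(roulette(big, 1e-4, 0.1)$weight)
  # survivor count is binomial(n, 0.1); 3-SE band on the total weight
  se <- 1e-4 * sqrt(2e4 * 0.1 * 0.9)
  expect_lt(abs(post - pre), 3 * se)
  expect_error(roulette(big, 1e-4, 1.2), "strictly in")
})
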