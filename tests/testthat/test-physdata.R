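test_that("interpolation reproduces tabulated knots and brackets midpoints", {
  cu <- load_material("cu")
  expect_equal(linear_attenuation(cu, cu$energy_kev),
               cu$density * cu$mu_rho, tolerance = 1e-12)
  # midpoint lies between the bracketing grid values
  for (i in c(2, 5, 8)) {
    mid <- sqrt(cu$energy_kev[i] * cu$energy_kev[i + 1])
    v <- linear_attenuation(cu, mid)
    expect_gt(v, cu$density * cu$mu_rho[i + 1])
    expect_lt(v, cu$density * cu$mu_rho[i])
  }
})

test_that("log-log interpolation matches a dense-grid brute-force oracle", {
  cu <- load_material("cu")
  # independent oracle: resample the two bracketing knots on a 0.01 keV grid
  # with the log-log line written out directly, then look up 43 keV
  dense_loglog <- function(e_query) {
    i <- max(which(cu$energy_kev <= e_query))
    grid <- seq(cu$energy_kev[i], cu$energy_kev[i + 1], by = 0.01)
    frac <- (log(grid) - log(cu$energy_kev[i])) /
      (log(cu$energy_kev[i + 1]) - log(cu$energy_kev[i]))
    vals <- exp(log(cu$mu_rho[i]) * (1 - frac) +
                  log(cu$mu_rho[i + 1]) * frac)
    cu$density * stats::approx(grid, vals, xout = e_query)$y
  }
  expect_equal(linear_attenuation(cu, 43), dense_loglog(43),
               tolerance = 1e-9)
  expect_equal(linear_attenuation(cu, 72.5), dense_loglog(72.5),
               tolerance = 1e-9)
})

test_that("bundled Cu, Al, air attenuation curves decrease over 10-150 keV", {
  for (m in c("cu", "al", "air")) {
    tab <- load_material(m)
    expect_true(all(diff(tab$mu_rho) < 0), info = m)
  }
})

test_that("HVL converts to the reference effective energies within 2%", {
  pairs <- data.frame(hvl = c(0.19, 0.30, 0.45, 0.55),
                      kev = c(42.9, 50.6, 58.6, 63.4))
  got <- hvl_to_effective_energy(pairs$hvl)
  expect_true(all(abs(got / pairs$kev - 1) < 0.02))
})

test_that("hvl<->energy round trips and is monotone", {
  x <- seq(0.1, 0.7, by = 0.05)
  back <- effective_energy_to_hvl(hvl_to_effective_energy(x))
  expect_equal(back, x, tolerance = 1e-8)
  e <- seq(15, 140, by = 5)
  expect_equal(hvl_to_effective_energy(effective_energy_to_hvl(e)), e,
               tolerance = 1e-8)
  expect_true(all(diff(hvl_to_effective_energy(x)) > 0))
  expect_true(all(diff(effective_energy_to_hvl(e)) > 0))
})

test_that("monoenergetic closed form and dense-grid inversion agree", {
  cu <- load_material("cu")
  expect_equal(effective_energy_to_hvl(60),
               10 * log(2) / linear_attenuation(cu, 60), tolerance = 1e-12)
  # brute-force inversion oracle: scan a dense energy grid for the best match
  target_hvl <- 0.42
  grid <- exp(seq(log(10), log(150), length.out = 200001))
  mu <- linear_attenuation(cu, grid)
  e_oracle <- grid[which.min(abs(10 * log(2) / mu - target_hvl))]
  expect_equal(hvl_to_effective_energy(target_hvl), e_oracle,
               tolerance = 1e-4)
})

test_that("out-of-range inputs raise range errors naming the bounds", {
  cu <- load_material("cu")
  expect_error(linear_attenuation(cu, 5), "range")
  expect_error(linear_attenuation(cu, 200), "range")
  expect_error(hvl_to_effective_energy(1e-4), "range")
  expect_error(hvl_to_effective_energy(50), "range")
  expect_error(hvl_to_effective_energy(-1), "positive")
})

test_that("material_table enforces its invariants", {
  e <- c(10, 20, 50, 150)
  expect_error(material_table("x", -1, e, e, e), "positive")
  expect_error(material_table("x", 1, c(10, 10, 50, 150), 1:4, 1:4),
               "increasing")
  expect_error(material_table("x", 1, c(20, 50, 150), 1:3, 1:3), "span")
  expect_error(material_table("x", 1, e, c(1, 2, -3, 4), 1:4), "positive")
  tab <- material_table("x", 2, e, c(4, 3, 2, 1), c(4, 3, 2, 1))
  expect_s3_class(tab, "material_table")
})
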