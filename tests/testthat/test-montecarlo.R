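# Deliberately small history counts: each check compares against an exact
# oracle within its own statistical resolution.

test_that("geometry validation rejects impossible configurations", {
  expect_error(pipe_geometry(pipe_wall = 0), "positive")
  expect_error(pipe_geometry(chamber_diameter = 13), "smaller")
  expect_error(transport(mono_beam(60), pipe_geometry(), 100, seed = 1),
               ">= 1000")
})

test_that("identical seeds give bit-identical simulated series", {
  s <- hardened_beam()
  g <- pipe_geometry(fan_half_angle_deg = 0.05)
  t_mm <- c(0.1, 0.2, 0.4, 0.6)
  a <- suppressWarnings(simulate_experiment(s, g, t_mm, 2e3, seed = 33))
  b <- suppressWarnings(simulate_experiment(s, g, t_mm, 2e3, seed = 33))
  expect_identical(a$exposures, b$exposures)
  c_ <- suppressWarnings(simulate_experiment(s, g, t_mm, 2e3, seed = 34))
  expect_false(identical(a$exposures, c_$exposures))
})

test_that("pencil-beam transmission matches Beer-Lambert within 3 SD", {
  mono <- mono_beam(60)
  g0 <- pipe_geometry(fan_half_angle_deg = 0, beam_width_at_iso = 0,
                      pipe_wall = 1e-9, rotating = FALSE)
  g <- pipe_geometry(fan_half_angle_deg = 0, beam_width_at_iso = 0,
                     pipe_wall = 0.3, rotating = FALSE)
  r0 <- transport(mono, g0, 2e4, seed = 7, air_scatter = FALSE)
  r1 <- transport(mono, g, 2e4, seed = 8, air_scatter = FALSE,
                  score_scatter = FALSE)
  mu <- linear_attenuation(load_material("cu"), 60)
  exact <- exp(-mu * 0.03)
  got <- r1$kerma_estimate / r0$kerma_estimate
  sd3 <- 3 * got * sqrt(r0$relative_error^2 + r1$relative_error^2)
  expect_lt(abs(got - exact), max(sd3, 3 * exact * r1$relative_error))
})

test_that("with no absorber the kerma matches the deterministic chord
           prediction", {
  # rotating fan: expected track length per photon from direct quadrature
  # over the fan angle (z-divergence negligible at this beam width)
  s <- hardened_beam()
  g <- pipe_geometry(fan_half_angle_deg = 0.3, beam_width_at_iso = 5,
                     pipe_wall = 1e-9)
  r <- transport(s, g, 4e4, seed = 12, air_scatter = FALSE)
  rc <- g$chamber_diameter / 2
  R <- g$source_to_isocenter
  fan <- g$fan_half_angle_deg * pi / 180
  chord <- function(a) {
    b <- R * sin(a)
    ifelse(abs(b) < rc, 2 * sqrt(rc^2 - b^2), 0)
  }
  mean_chord <- stats::integrate(chord, -fan, fan)$value / (2 * fan)
  air <- load_material("air")
  mean_kerma_per_len <- sum(s$fluence * s$energy_kev *
                              mass_energy_absorption(air, s$energy_kev)) /
    sum(s$fluence)
  predicted <- mean_chord * mean_kerma_per_len
  expect_lt(abs(r$kerma_estimate - predicted),
            3 * predicted * max(r$relative_error, 1e-3))
})

test_that("relative error shrinks like one over root n", {
  s <- hardened_beam()
  g <- pipe_geometry(fan_half_angle_deg = 0.05, pipe_wall = 0.3)
  # doubling the histories should shrink the error by ~1/sqrt(2); use many
  # batches and a few seed pairs to beat the noise of the SE estimate itself
  ratios <- vapply(1:3, function(k) {
    r1 <- transport(s, g, 2e4, seed = 100 + k, n_batches = 40)
    r2 <- transport(s, g, 4e4, seed = 200 + k, n_batches = 40)
    r2$relative_error / r1$relative_error
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1 / sqrt(2)), 0.3 / sqrt(2))
})

test_that("a beam that cannot reach the chamber raises a zero-score error", {
  # wall so thick the transmitted fluence vanishes
  g <- pipe_geometry(fan_half_angle_deg = 0.05, pipe_wall = 60)
  expect_error(transport(mono_beam(40), g, 2e3, seed = 1,
                         score_scatter = FALSE, air_scatter = FALSE),
               "misses the chamber")
})

test_that("monoenergetic end-to-end simulation recovers the closed-form HVL", {
  mono <- mono_beam(60)
  g <- pipe_geometry(fan_half_angle_deg = 0.02, beam_width_at_iso = 2)
  ser <- suppressWarnings(
    simulate_experiment(mono, g, c(0.1, 0.2, 0.3, 0.4, 0.5), 5e4, seed = 3,
                        score_scatter = FALSE, air_scatter = FALSE))
  r <- suppressWarnings(analyze_series(ser))
  exact <- 10 * log(2) / linear_attenuation(load_material("cu"), 60)
  expect_lt(abs(r$hvl_mm / exact - 1), 0.02)
})

test_that("scored scatter grows when the pipe no longer shields the chamber", {
  # ambient (bore air) scatter amplified 30x so the shielding signal rises
  # above batch resolution; the pipe-length effect is what is asserted
  s <- hardened_beam()
  sf <- vapply(c(100, 10), function(L) {
    g <- pipe_geometry(fan_half_angle_deg = 0.05, beam_width_at_iso = 5,
                       pipe_length = L, pipe_wall = 0.3)
    transport(s, g, 5e4, seed = 5, air_density_scale = 30)$scatter_fraction
  }, numeric(1))
  expect_gt(sf[2], sf[1])
  expect_true(all(sf >= 0 & sf <= 1))
})

test_that("Compton-disabled transport equals the attenuation-only model", {
  # with compton = FALSE every interaction absorbs: transmission through a
  # slanted wall equals the Beer-Lambert factor for the traversed path
  mono <- mono_beam(80)
  g <- pipe_geometry(fan_half_angle_deg = 0, beam_width_at_iso = 0,
                     pipe_wall = 0.4, rotating = FALSE)
  g0 <- g; g0$pipe_wall <- 1e-9
  r <- transport(mono, g, 2e4, seed = 4, compton = FALSE,
                 air_scatter = FALSE)
  r0 <- transport(mono, g0, 2e4, seed = 4, compton = FALSE,
                  air_scatter = FALSE)
  mu <- linear_attenuation(load_material("cu"), 80)
  got <- r$kerma_estimate / r0$kerma_estimate
  exact <- exp(-mu * 0.04)
  expect_lt(abs(got - exact), 3 * exact * max(r$relative_error, 1e-3))
  expect_identical(r$scatter_fraction, 0)
})
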