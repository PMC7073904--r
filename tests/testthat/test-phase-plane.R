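test_that("phase-plane slope equals the toy model's analytic demand", {
  for (b in c(0.1, 0.54, 0.7, 5, 20)) {
    pp <- toy_thy(b)
    expect_lte(abs(pp$slope - b) / b, 1e-6)
    expect_lt(abs(pp$intercept), 1e-9)
    expect_false(pp$intercept_flagged)
    # envelope sanity at every feasible point
    ok <- pp$grid$feasible
    expect_true(all(pp$grid$min_flux[ok] <= pp$grid$max_flux[ok] + 1e-9))
    expect_true(all(diff(pp$grid$min_flux[ok]) >= -1e-9))
  }
})

test_that("methionine supplementation can only lower the slope", {
  m <- gen_toy_model(0.7, "auxotroph")
  slope_thy <- phase_plane(m, build_medium("thy"))$slope
  slope_met <- phase_plane(m, build_medium("thy_met"))$slope
  expect_lt(slope_met, slope_thy)
  expect_equal(slope_met, 0.54, tolerance = 1e-6)
})

test_that("the slope reflects stoichiometric demand, not carbon supply", {
  m <- gen_toy_model(0.7, "auxotroph")
  pp10 <- phase_plane(m, build_medium("thy", glc_uptake = 10))
  pp20 <- phase_plane(m, build_medium("thy", glc_uptake = 20))
  expect_equal(pp20$slope, pp10$slope, tolerance = 1e-9)
  expect_gt(pp20$mu_max, pp10$mu_max)  # supply moved, stoichiometry did not
})

test_that("decoy pathways never shift the envelope", {
  pp_a <- toy_thy(0.7, seed = 1, n_filler = 3)
  pp_b <- toy_thy(0.7, seed = 99, n_filler = 8)
  expect_equal(pp_b$slope, pp_a$slope, tolerance = 1e-9)
})

test_that("phase_plane validates its inputs", {
  m <- gen_toy_model(0.7, "auxotroph")
  med <- build_medium("thy")
  expect_error(phase_plane(m, med, reaction_id = "NOPE"), "NOPE")
  expect_error(phase_plane(m, med, growth_grid = c(0.1, 0.2)),
               "3 points")
  expect_error(phase_plane(m, med, growth_grid = c(0.2, 0.1, 0.3)),
               "increasing")
  expect_error(phase_plane(m, med, growth_grid = c(5, 6, 7)), "shrink")
})

test_that("flux derivation intersects the envelope with the measured rate", {
  pp <- toy_thy(0.7)
  fe <- derive_flux(pp, growth_measurement(0.036, 0.006, 18))
  expect_equal(fe$flux, 0.7 * 0.036, tolerance = 1e-6)
  expect_equal(fe$sd, 0.7 * 0.006, tolerance = 1e-6)
  pp54 <- phase_plane(gen_toy_model(0.7, "auxotroph"),
                      build_medium("thy_met"))
  fe54 <- derive_flux(pp54, growth_measurement(0.047, 0.004, 18))
  expect_equal(fe54$flux, 0.54 * 0.047, tolerance = 1e-6)
  expect_equal(fe54$sd, 0.54 * 0.004, tolerance = 1e-6)
  # mu = 0 returns the intercept
  fe0 <- derive_flux(pp, growth_measurement(0, 0, 2))
  expect_equal(fe0$flux, pp$intercept)
  expect_error(derive_flux(pp, growth_measurement(5, 0.1, 3)),
               "outside the feasible range")
})

test_that("error propagation through both derivations is exactly linear", {
  pp <- toy_thy(0.7)
  for (sd_in in c(0.001, 0.006, 0.02)) {
    fe <- derive_flux(pp, growth_measurement(0.036, sd_in, 18))
    expect_equal(fe$sd / sd_in, pp$slope, tolerance = 1e-9)
  }
  pps <- phase_plane(gen_toy_model(20.8, "serine"),
                     build_medium("formaldehyde_only"))
  fe <- derive_flux(toy_thy(0.7), growth_measurement(0.036, 0.006, 18))
  mg <- derive_max_growth(pps, fe)
  expect_equal(mg$sd * pps$slope, fe$sd, tolerance = 1e-9)
})

test_that("the serine-cycle bound inverts the phase plane", {
  pps <- phase_plane(gen_toy_model(20.8, "serine"),
                     build_medium("formaldehyde_only"))
  expect_gt(pps$slope, 20)
  fe <- derive_flux(toy_thy(0.7), growth_measurement(0.036, 0.006, 18))
  mg <- derive_max_growth(pps, fe)
  expect_equal(mg$mean_mu, fe$flux / pps$slope, tolerance = 1e-9)
  expect_equal(mg$mean_mu, 0.0012, tolerance = 0.02)
  # closure: back through the same plane returns the flux
  expect_equal(derive_flux(pps, growth_measurement(mg$mean_mu, mg$sd, 18))$flux,
               fe$flux, tolerance = 1e-9)
  # slope 20 exactly, flux 0.025: mu = 0.00125 by arithmetic
  pp20 <- phase_plane(gen_toy_model(20, "serine"),
                      build_medium("formaldehyde_only"))
  fe25 <- structure(list(flux = 0.025, sd = 0.004,
                         growth = growth_measurement(0.036, 0.006, 18)),
                    class = "flux_estimate")
  expect_equal(derive_max_growth(pp20, fe25)$mean_mu,
               (0.025 - pp20$intercept) / pp20$slope, tolerance = 1e-9)
  expect_equal(derive_max_growth(pp20, fe25)$mean_mu, 0.00125,
               tolerance = 1e-6)
  # a non-positive slope cannot be inverted
  flat <- pps; flat$slope <- 0
  expect_error(derive_max_growth(flat, fe), "positive")
})

test_that("phase planes export to TSV and JSON", {
  pp <- toy_thy(0.7)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_phase_plane(pp, tsv, js)
  grid <- utils::read.delim(tsv)
  expect_identical(nrow(grid), nrow(pp$grid))
  meta <- jsonlite::read_json(js)
  expect_equal(meta$slope, pp$slope)
})
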