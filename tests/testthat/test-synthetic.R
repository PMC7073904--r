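test_that("generators are bit-reproducible per seed and leave the RNG alone", {
  g1 <- gen_growth_curve(seed = 42)
  set.seed(1); before <- stats::runif(1)
  g2 <- gen_growth_curve(seed = 42)
  set.seed(1); after <- stats::runif(1)
  expect_identical(g1, g2)
  expect_identical(before, after)
  f1 <- gen_formaldehyde_series(mode = "growing_plateau", seed = 7)
  f2 <- gen_formaldehyde_series(mode = "growing_plateau", seed = 7)
  expect_identical(f1, f2)
  expect_false(identical(gen_growth_curve(seed = 1)$od600,
                         gen_growth_curve(seed = 2)$od600))
})

test_that("noiseless growth curves satisfy the generating equations pointwise", {
  mu <- 0.036; n0 <- 0.02; lag <- 5; cap <- 0.9
  g <- gen_growth_curve(mu = mu, n0 = n0, lag = lag, capacity = cap,
                        noise_cv = 0)
  s <- pmax(0, g$time_h - lag)
  expo <- n0 * exp(mu * s)
  below <- expo <= cap / 2
  expect_equal(g$od600[below], expo[below], tolerance = 1e-12)
  # lag phase is flat at the inoculum
  expect_equal(g$od600[g$time_h <= lag], rep(n0, sum(g$time_h <= lag)),
               tolerance = 1e-12)
  # saturation approaches but never exceeds the carrying capacity
  expect_true(all(g$od600 <= cap + 1e-9))
  expect_gt(max(g$od600), 0.8 * cap)
})

test_that("formaldehyde series show the two experimental regimes", {
  acc <- gen_formaldehyde_series("non_growing_accumulation", noise_sd = 0,
                                 times = seq(0, 120, by = 4))
  expect_true(all(diff(acc$conc_true_uM) > 0))
  expect_gt(max(acc$conc_true_uM), 900)   # heads towards ~1000 uM
  expect_lt(max(acc$conc_true_uM), 1000)
  gro <- gen_formaldehyde_series("growing_plateau", noise_sd = 0,
                                 plateau_uM = 100,
                                 times = seq(0, 120, by = 4))
  expect_equal(max(gro$conc_true_uM), 100, tolerance = 1e-9)
  # declines after stationary onset
  expect_lt(gro$conc_true_uM[length(gro$conc_true_uM)], 100)
})

test_that("generated Nash absorbances close the loop with the calibration", {
  std <- gen_nash_standards(slope = 1.2, intercept = 0.05, noise_sd = 0.01,
                            seed = 3)
  cal <- calibrate_nash(std)
  expect_lt(abs(cal$slope - 1.2) / 1.2, 0.05)
  ser <- gen_formaldehyde_series("growing_plateau", seed = 3,
                                 cal_slope = 1.2, cal_intercept = 0.05)
  est_uM <- as.numeric(nash_invert(cal, ser$absorbance)) * 1000
  # recovered concentrations track the generated ones
  expect_lt(sqrt(mean((est_uM - ser$conc_uM)^2)), 15)
})

test_that("toy models are mass balanced at every computed optimum", {
  for (spec in list(c("auxotroph", 0.7), c("serine", 20.8))) {
    m <- gen_toy_model(as.numeric(spec[2]), spec[1])
    med <- build_medium(if (spec[1] == "serine") "formaldehyde_only" else "thy")
    withmed <- apply_medium(m, med)
    sol <- fba(withmed)
    expect_identical(sol$status, "optimal")
    expect_lte(max(abs(stoichiometric_matrix(withmed) %*% sol$fluxes)), 1e-9)
  }
})

test_that("toy generation validates parameters and reports its analytic answers", {
  expect_error(gen_toy_model(0), "b > 0")
  expect_error(gen_toy_model(1, met_share = 1.2), "met_share")
  m <- gen_toy_model(0.7, "auxotroph")
  expect_equal(attr(m, "slope"), 0.7)
  expect_equal(attr(m, "slope_met"), 0.54, tolerance = 1e-12)
  expect_equal(attr(m, "mu_max"), 1)
  s <- gen_toy_model(20.8, "serine")
  expect_equal(attr(s, "mu_max"), 1000 / 20.8)
})

test_that("uncurated toys plus the recipes equal the curated toys", {
  for (spec in list(c("auxotroph", 0.7), c("serine", 20.8))) {
    b <- as.numeric(spec[2])
    cur <- gen_toy_model(b, spec[1], curated = TRUE)
    raw <- gen_toy_model(b, spec[1], curated = FALSE)
    built <- apply_curation(raw, base_curation_recipe())
    if (spec[1] == "serine") {
      built <- apply_curation(built, serine_cycle_recipe())
    }
    expect_identical(canonical_model(built), canonical_model(cur))
  }
})

test_that("the uncurated auxotroph does not need formaldehyde, the curated one does", {
  raw <- gen_toy_model(0.7, "auxotroph", curated = FALSE)
  # before the knockouts, glycine cleavage supplies 5,10-methylene-THF, but
  # thymidine cannot be imported (the symporter still runs outward only)
  med <- build_medium("thy")
  raw_med <- apply_medium(raw, med)
  raw_med$reactions[["EX_fald_e"]]$lower_bound <- 0
  expect_error(fba(raw_med), NA)
  cur <- apply_medium(gen_toy_model(0.7, "auxotroph"), med)
  cur$reactions[["EX_fald_e"]]$lower_bound <- 0
  expect_equal(fba(cur)$objective, 0, tolerance = 1e-9)
})
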