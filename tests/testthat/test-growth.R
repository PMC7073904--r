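test_that("growth_curve validates its inputs", {
  expect_error(growth_curve(c(0, 1, 1.5, 1.2), rep(0.1, 4)), "increasing")
  expect_error(growth_curve(0:3, c(0.1, -0.2, 0.3, 0.4)), "positive")
})

test_that("noiseless exponentials are recovered to machine precision", {
  tt <- seq(0, 10, by = 0.5)
  curve <- growth_curve(tt, 0.02 * exp(0.25 * tt))
  fit <- fit_exponential(curve)
  expect_equal(fit$mu, 0.25, tolerance = 1e-12)
  expect_equal(fit$n0, 0.02, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_gte(diff(fit$window) + 1, 4)
  # window choice cannot matter on a pure exponential
  fit_narrow <- fit_exponential(curve, od_range = c(0.03, 0.2))
  expect_equal(fit_narrow$mu, 0.25, tolerance = 1e-12)
})

test_that("declining or erratic curves raise a fit failure with diagnostics", {
  tt <- seq(0, 10, by = 1)
  expect_error(fit_exponential(growth_curve(tt, 0.5 * exp(-0.2 * tt))),
               "mu")
  set.seed(4)
  expect_error(
    fit_exponential(growth_curve(tt, stats::runif(11, 0.04, 0.5))),
    "r2")
  expect_error(fit_exponential(growth_curve(0:3, rep(0.1, 4))),
               "at least 6")
})

test_that("seeded synthetic curves return the generating rate within its uncertainty", {
  mus <- vapply(1:20, function(s) {
    fit_exponential(gen_growth_curve(mu = 0.036, noise_cv = 0.03,
                                     seed = s))$mu
  }, numeric(1))
  expect_lt(abs(mean(mus) - 0.036), stats::sd(mus))
  for (s in c(2, 9)) {
    fit <- fit_exponential(gen_growth_curve(mu = 0.036, noise_cv = 0.03,
                                            seed = s))
    expect_lt(abs(fit$mu - 0.036), 2 * max(fit$mu_sd, stats::sd(mus)))
  }
})

test_that("doubling time inverts the growth rate", {
  expect_equal(doubling_time(0.0012), 577.62, tolerance = 1e-4)
  expect_equal(doubling_time(log(2)), 1)
  expect_equal(doubling_time(0.25), log(2) / 0.25, tolerance = 1e-12)
  for (mu in c(1e-4, 0.036, 0.25, 3)) {
    expect_equal(doubling_time(mu) * mu, log(2), tolerance = 1e-12)
  }
  expect_error(doubling_time(0), "mu <= 0")
  expect_error(doubling_time(-1), "mu <= 0")
})

test_that("summary-statistic Welch test matches t.test on reconstructed samples", {
  cases <- list(list(c(0.037, 0.007, 9), c(0.035, 0.005, 9)),
                list(c(0.047, 0.004, 18), c(0.036, 0.006, 18)),
                list(c(1.2, 0.3, 5), c(0.9, 0.2, 12)))
  for (cs in cases) {
    a <- cs[[1]]; b <- cs[[2]]
    p <- compare_groups(a, b)
    oracle <- stats::t.test(vector_with_moments(a[1], a[2], a[3]),
                            vector_with_moments(b[1], b[2], b[3]))$p.value
    expect_equal(p, oracle, tolerance = 1e-9)
  }
})

test_that("the growth-rate comparisons behave like the reported experiments", {
  p_pan <- compare_groups(c(0.037, 0.007, 9), c(0.035, 0.005, 9))
  expect_gt(p_pan, 0.4)
  p_met <- compare_groups(c(0.047, 0.004, 18), c(0.036, 0.006, 18))
  expect_lt(p_met, 1e-5)
})

test_that("compare_groups is symmetric, scale-invariant, and handles degeneracy", {
  a <- c(0.04, 0.01, 6); b <- c(0.05, 0.02, 8)
  expect_equal(compare_groups(a, b), compare_groups(b, a), tolerance = 1e-12)
  expect_equal(compare_groups(a * c(10, 10, 1), b * c(10, 10, 1)),
               compare_groups(a, b), tolerance = 1e-12)
  expect_equal(compare_groups(a, a), 1)
  expect_equal(compare_groups(c(1, 0, 5), c(1, 0, 5)), 1)
  expect_equal(compare_groups(c(1, 0, 5), c(2, 0, 5)), 0)
})

test_that("Nash calibration recovers an exact line and inverts it", {
  std <- data.frame(mM = seq(0, 1, by = 0.25),
                    absorbance = 1.2 * seq(0, 1, by = 0.25) + 0.05)
  cal <- calibrate_nash(std)
  expect_equal(cal$slope, 1.2, tolerance = 1e-12)
  expect_equal(cal$intercept, 0.05, tolerance = 1e-12)
  expect_equal(as.numeric(nash_invert(cal, 0.65)), 0.5, tolerance = 1e-12)
  # calibrate -> invert is the identity on collinear standards
  back <- nash_invert(cal, std$absorbance)
  expect_equal(as.numeric(back), std$mM, tolerance = 1e-12)
  expect_false(any(attr(back, "out_of_range")))
})

test_that("noisy standards still recover the calibration within 5%", {
  std <- gen_nash_standards(slope = 1.2, intercept = 0.05, noise_sd = 0.01,
                            seed = 5)
  cal <- calibrate_nash(std)
  expect_lt(abs(cal$slope - 1.2) / 1.2, 0.05)
})

test_that("out-of-range inversions are flagged, non-monotone standards rejected", {
  cal <- calibrate_nash(data.frame(mM = c(0, 0.5, 1),
                                   absorbance = c(0.05, 0.65, 1.25)))
  high <- nash_invert(cal, 1.5)  # above the 1 mM-equivalent absorbance
  expect_true(attr(high, "out_of_range"))
  expect_gt(as.numeric(high), 1)
  expect_error(calibrate_nash(data.frame(mM = c(0, 0.5, 1),
                                         absorbance = c(1, 0.5, 0.1))),
               "calibration error")
  expect_error(calibrate_nash(data.frame(mM = c(0, 1),
                                         absorbance = c(0, 1))), ">= 3")
})
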