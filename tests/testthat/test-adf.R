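test_that("37-percent rule recovers the constant of an exact exponential", {
  x <- seq(0, 3000, by = 5)
  p <- attenuation_profile(x, 15 * exp(-x / 500), origin = 15)
  sc <- space_constant(p)
  expect_equal(sc$status, "ok")
  expect_equal(sc$value, 500 * log(1 / 0.37), tolerance = 1e-4)
  expect_equal(sc$value, 497.1, tolerance = 1e-3)
  # the threshold itself: 37 percent of a 15 mV source is 5.55 mV
  expect_equal(sc$threshold, 5.55)
})

test_that("non-monotonic and non-crossing profiles are refused or flagged", {
  x <- seq(0, 1000, by = 100)
  flat <- attenuation_profile(x, rep(10, length(x)), origin = 10)
  expect_equal(space_constant(flat)$status, "no_crossing")
  rise <- attenuation_profile(x, 10 + 0.5 * sin(x / 150), origin = 10)
  expect_equal(space_constant(rise)$status, "biphasic")
  # a sub-tolerance ripple on a decaying profile is not biphasic
  ok <- attenuation_profile(x, 10 * exp(-x / 300) + 0.004 * (x %% 200 == 0), origin = 10)
  expect_equal(space_constant(ok)$status, "ok")
  expect_error(attenuation_profile(c(0, 10, 5), 1:3), "strictly increasing")
})

test_that("per-site facilitation is the conditioned/control EPSP percentage", {
  expect_equal(adf_at_site(1, 1), 100)
  expect_equal(adf_at_site(1, 1.368), 136.8)
  expect_equal(adf_at_site(2, 2.654), 132.7)
  expect_error(adf_at_site(0, 1), "positive")
})

test_that("spatial extent is the last downward 105-percent crossing", {
  # two-point closed form: 140% at 100 um, 101% at 1000 um
  e <- adf_spatial_extent(c(100, 1000), c(140, 101))
  expect_equal(e$status, "ok")
  expect_equal(e$value, 100 + 900 * 35 / 39, tolerance = 1e-9)
  expect_equal(e$value, 907.7, tolerance = 1e-4)
  # flat at control: zero extent
  expect_equal(adf_spatial_extent(c(100, 1000), c(100, 100))$status, "none")
  # never dropping below the level: flagged unbounded
  eu <- adf_spatial_extent(c(100, 500, 1000), c(140, 120, 110))
  expect_equal(eu$status, "unbounded")
  expect_true(is.infinite(eu$value))
  # proximal dip then recovery: the LAST downward crossing wins
  e2 <- adf_spatial_extent(c(100, 200, 300, 400), c(110, 104, 110, 100))
  expect_gt(e2$value, 300)
  expect_error(adf_spatial_extent(100, 140), "at least two")
})

test_that("site fractions and qualifying distances are computed correctly", {
  adf <- c(110, 106, 104, 100, 100)
  d <- c(100, 200, 300, 400, 500)
  f <- site_fraction_ge(adf, d, threshold = 5)
  expect_equal(f$fraction_pct, 40)
  expect_equal(f$mean_dist, 150)
  expect_equal(f$sd_dist, stats::sd(c(100, 200)))
  z <- site_fraction_ge(rep(100, 4), d[1:4])
  expect_equal(z$fraction_pct, 0)
  expect_true(is.na(z$mean_dist))
  expect_error(site_fraction_ge(numeric(0), numeric(0)), "empty")
})

test_that("wraps-curve fit recovers parameters", {
  n <- c(0, 2, 5, 10, 15, 20)
  truth <- c(a = 313.24, b = 636.2, cc = 0.189)
  sp <- truth["a"] + truth["b"] * (1 - exp(-truth["cc"] * n))
  fit <- fit_wraps_curve(n, sp)
  expect_equal(fit$a, truth[["a"]], tolerance = 1e-6)
  expect_equal(fit$b, truth[["b"]], tolerance = 1e-6)
  expect_equal(fit$c, truth[["cc"]], tolerance = 1e-6)
  # with seeded Gaussian noise the parameters come back within a few percent
  set.seed(42)
  spn <- sp + stats::rnorm(length(n), sd = 5)
  fitn <- fit_wraps_curve(n, spn)
  expect_equal(fitn$a, truth[["a"]], tolerance = 0.05)
  expect_equal(fitn$b, truth[["b"]], tolerance = 0.10)
  expect_equal(fitn$c, truth[["cc"]], tolerance = 0.25)
  expect_error(fit_wraps_curve(c(2, 5, 10, 15), sp[2:5]), "N = 0")
  expect_error(fit_wraps_curve(c(0, 5), sp[c(1, 3)]), ">= 4")
})
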