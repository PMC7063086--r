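test_that("sheath thickness follows the g-ratio geometry", {
  # reference fiber: g = 0.698, r_ax = 0.57 um, periaxonal 12.3 nm
  expect_equal(myelin_thickness(0.698, 0.57, 0.0123), 0.234, tolerance = 0.0025)
  # t_p = 0 and g = 1/2 make the sheath exactly one radius thick
  expect_equal(myelin_thickness(0.5, 1, 0), 1)
  # closed form at an arbitrary point
  g <- 0.95; r <- 0.57; tp <- 0.0123
  expect_equal(myelin_thickness(g, r, tp), r * (1 / g - 1) - tp)
  expect_error(myelin_thickness(1, 0.57), "between 0 and 1")
  expect_error(myelin_thickness(0.2, 0.01, 0.5), "impossible")
})

test_that("wrap count is sheath thickness over two membranes", {
  expect_equal(wraps_from_thickness(0.234, 0.0075), 15.6, tolerance = 1e-3)
  expect_equal(wraps_from_thickness(0, 0.0075), 0)
  expect_equal(wraps_from_thickness(0.03, 0.0075), 2)
  expect_error(wraps_from_thickness(-1), ">= 0")
})

test_that("geometric chain recovers 15.6 wraps for the reference fiber", {
  w <- wraps_from_thickness(myelin_thickness(0.698, 0.57, 0.0123), 0.0075)
  expect_equal(w, 15.6, tolerance = 0.05 / 15.6)
  sh <- myelin_sheath()
  expect_equal(sh$wraps_geometric, w)
  expect_identical(sh$n, 15L) # the applied integer wrap count
})

test_that("sheath RC divides the axolemma values by twice the wrap count", {
  rc15 <- sheath_rc(15, 0.333, 1)
  expect_equal(rc15$G_my, 0.333 / 30)
  expect_equal(rc15$C_my, 1 / 30)
  rc2 <- sheath_rc(2, 0.333, 1)
  expect_equal(rc2$G_my, 0.333 / 4)
  expect_equal(rc2$C_my, 1 / 4)
  rc0 <- sheath_rc(0)
  expect_false(rc0$has_sheath)
  expect_error(sheath_rc(-1), "non-negative")
  expect_error(sheath_rc(2.5), "integer")
})

test_that("sheath RC is strictly decreasing and halves when wraps double", {
  ns <- c(1, 2, 4, 8, 16, 32)
  g <- vapply(ns, function(n) sheath_rc(n)$G_my, 0)
  cc <- vapply(ns, function(n) sheath_rc(n)$C_my, 0)
  expect_true(all(diff(g) < 0))
  expect_true(all(diff(cc) < 0))
  expect_equal(g[-1] / g[-length(g)], rep(0.5, 5))
  expect_equal(cc[-1] / cc[-length(cc)], rep(0.5, 5))
})
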