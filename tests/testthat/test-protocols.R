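test_that("spike metrics match closed forms on a synthetic triangular spike", {
  # triangle: baseline -70, peak +30, rise 0.2 ms, fall 0.4 ms
  t <- seq(0, 5, by = 1e-3)
  peak_t <- 2
  v <- -70 + pmax(0, pmin((t - (peak_t - 0.2)) / 0.2, (peak_t + 0.4 - t) / 0.4)) * 100
  m <- spike_metrics(t, v, area_ref = -70, area_gate = -20)
  expect_equal(m$overshoot, 30, tolerance = 1e-3)
  expect_equal(m$amplitude, 100, tolerance = 1e-3)
  # half-width: time between the 50% crossings = (0.2 + 0.4) / 2
  expect_equal(m$half_width, 0.3, tolerance = 1e-3)
  # area above -70 while V > -20: triangle above half the height
  # width at the gate = 0.6 * (1 - 50/100)... piecewise: rise 0.1, fall 0.2
  gate_area <- 0.5 * (0.1 + 0.2) * 50 + (0.1 + 0.2) * 50
  expect_equal(m$area, gate_area, tolerance = 0.01)
})

test_that("spike metrics refuse windows without exactly one spike", {
  t <- seq(0, 5, by = 1e-3)
  expect_error(spike_metrics(t, rep(-70, length(t))), "found 0")
  v2 <- -70 + 100 * (exp(-((t - 1) / 0.1)^2) + exp(-((t - 3) / 0.1)^2))
  expect_error(spike_metrics(t, v2), "found 2")
})

test_that("Ca charge integrates the inward transient", {
  t <- seq(0, 5, by = 1e-3)
  ica <- ifelse(t >= 1 & t < 2, -1, 0)
  expect_equal(ca_charge(t, ica), 1, tolerance = 1e-3) # 1 nA x 1 ms
  # standing current is subtracted
  expect_equal(ca_charge(t, ica - 0.2), 1, tolerance = 1e-3)
  expect_error(ca_charge(numeric(0), numeric(0)), "empty")
})

test_that("release follows the 2.5-power law of the Ca charge", {
  expect_equal(synaptic_weight(0, a = 2), 0)
  expect_equal(synaptic_weight(2, a = 3) / synaptic_weight(1, a = 3), 2^2.5)
  expect_equal(2^2.5, 5.657, tolerance = 1e-4)
  # the reference modulation: Q ratio 1.134 -> transmission ratio 1.369
  expect_equal(1.134^2.5, 1.369, tolerance = 1e-3)
  expect_error(synaptic_weight(-1), "non-negative")
})

test_that("EPSP amplitude is linear in weight for small responses", {
  expect_equal(epsp_amplitude(0), 0)
  w1 <- 1e-4
  a1 <- epsp_amplitude(w1)
  a2 <- epsp_amplitude(2 * w1)
  expect_equal(a2 / a1, 2, tolerance = 0.05)
  # vectorized and monotone
  ww <- c(1e-5, 1e-4, 1e-3, 5e-3)
  aa <- epsp_amplitude(ww)
  expect_true(all(diff(aa) > 0))
  expect_error(epsp_amplitude(-1), ">= 0")
})

test_that("EPSP facilitation propagates the power law end to end", {
  # criterion: facilitation ratio equals (Q ratio)^2.5 within 2 percent in
  # the linear-EPSP regime
  syn <- synapse_model()
  q <- c(1, 1.134)
  a_scale <- 1e-4 # control EPSP ~ 1 mV scale
  w <- synaptic_weight(q, a_scale)
  eps <- epsp_amplitude(w, syn)
  ratio <- eps[2] / eps[1]
  expect_equal(ratio, q[2]^2.5, tolerance = 0.02)
})

test_that("zero-amplitude conditioning reproduces the rest-spike traces", {
  mod <- small_active_model()
  r <- small_rest(mod)
  p0 <- stim_protocol("dadf", cond_amp = 0, cond_dur = 100, window_ms = 12)
  pr <- stim_protocol("rest", window_ms = 12)
  a <- run_protocol(mod, p0, sites = 1L, rest = r)
  b <- run_protocol(mod, pr, sites = 1L, rest = r)
  expect_lt(max(abs(a$site_V - b$site_V)), 1e-6)
  expect_lt(max(abs(a$cond_V - r$V)), 1e-9)
})

test_that("the protocol machinery reports conditioning and spikes per site", {
  mod <- small_active_model()
  r <- small_rest(mod)
  tr <- run_protocol(mod, stim_protocol("dadf", window_ms = 15), sites = c(1L, 10L),
                     rest = r)
  # the conditioning depolarizes the sites by a few mV
  dv <- (tr$cond_V - r$V)[mod$site_comp[c(1, 10)]]
  expect_true(all(dv > 2 & dv < 15))
  # exactly one spike at each recorded site
  for (k in 1:2) {
    expect_equal(adfsim:::.count_spikes(tr$site_V[k, ]), 1)
  }
  expect_equal(dim(tr$site_ICa), dim(tr$site_V))
})
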