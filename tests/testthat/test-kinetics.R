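test_that("gating steady states stay in [0,1] and taus are positive", {
  kin <- default_kinetics()
  v <- seq(-100, 60, by = 0.5)
  for (ch in c("nav12", "nav16", "kdr", "kv1", "capq")) {
    g <- gate_steady(kin[[ch]], v)
    for (gate in g) {
      expect_true(all(gate$inf >= 0 & gate$inf <= 1), info = ch)
      expect_true(all(gate$tau > 0), info = ch)
    }
    of <- open_fraction_steady(kin[[ch]], v)
    expect_true(all(of >= 0 & of <= 1), info = ch)
  }
})

test_that("steady-state initialization agrees with relaxing the gate ODEs", {
  # independent oracle: integrate dy/dt = (y_inf - y)/tau at clamped V from a
  # remote start; after many time constants it must land on init_steady_state
  kin <- default_kinetics()
  v <- -63.7
  target <- init_steady_state(v, kin)
  relax <- function(kinent, gate, y0) {
    g <- gate_steady(kinent, v)[[gate]]
    y <- y0
    dt <- g$tau / 50
    for (i in seq_len(ceiling(25 * g$tau / dt))) y <- y + dt * (g$inf - y) / g$tau
    y
  }
  expect_equal(relax(kin$nav16, "m", 0.9), target$m16, tolerance = 1e-6)
  expect_equal(relax(kin$nav16, "h", 0.1), target$h16, tolerance = 1e-6)
  expect_equal(relax(kin$kdr, "n", 0.9), target$n_kdr, tolerance = 1e-6)
  expect_equal(relax(kin$kv1, "m", 0.9), target$m_kv1, tolerance = 1e-6)
  expect_equal(relax(kin$capq, "m", 0.9), target$m_ca, tolerance = 1e-6)
})

test_that("a model initialized at its rest state does not drift", {
  mod <- small_active_model()
  r <- small_rest(mod)
  out <- run_sim(mod, r, dt = 0.5, t_ms = 1000,
                 record = c(mod$soma_comp, mod$node_comp[1]), rec_stride = 100)
  expect_true(all(abs(out$V - r$V[c(mod$soma_comp, mod$node_comp[1])]) < 0.1))
})
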