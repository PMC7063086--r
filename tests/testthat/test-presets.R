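test_that("the nine presets carry the reference density table", {
  expect_length(preset_names(), 9)
  nm <- load_preset("NonMyelinated")
  expect_equal(nm$axon$node$nav16, 370)
  expect_equal(nm$axon$node$kv1, 26.8)
  expect_equal(nm$axon$internode$nav16, 370)
  expect_equal(nm$axon$e_leak, -38.3)
  expect_equal(nm$wraps, 0L)
  expect_null(nm$sheath)

  m1 <- load_preset("Myelin1")
  expect_equal(m1$axon$node$nav16, 1184.4)
  expect_equal(m1$axon$node$kv1, 85.5)
  expect_equal(m1$axon$internode$nav16, 0)
  expect_equal(m1$axon$internode$kv1, 0)
  expect_equal(m1$sheath$G_my, 0.333 / 30)
  expect_equal(m1$sheath$C_my, 1 / 30)

  m4 <- load_preset("Myelin4")
  expect_equal(m4$wraps, 2L)
  expect_equal(m4$axon$node$nav16, 6016)
  expect_equal(m4$axon$node$kv1, 393)
  expect_equal(m4$sheath$G_my, 0.333 / 4)

  hy <- load_preset("Hybrid")
  expect_equal(hy$axon$node$nav16, 1184.4) # node-like hot spots
  expect_equal(hy$axon$internode$nav16, 370) # on non-myelinated stretches
  expect_null(hy$sheath)

  # common rows of the table
  for (nm in preset_names()) {
    p <- load_preset(nm)
    expect_equal(p$axon$leak, 0.333)
    expect_equal(p$axon$c_m, 1)
    expect_equal(p$axon$node$capq, 1)
    expect_equal(p$somatodendritic$soma$nav12, 80)
  }
  expect_error(load_preset("Myelin99"), "NonMyelinated.*Myelin7")
})

test_that("leak-reversal calibration balances the standing currents", {
  # a region with no voltage-gated channels rests exactly at E_leak
  expect_equal(calibrate_eleak(list(leak = 0.333), -70), -70)
  # somatodendritic channels barely move it
  e_sd <- calibrate_eleak(list(leak = 0.333, nav12 = 80, kdr = 20), -70)
  expect_lt(abs(e_sd - (-69.5)), 1)
  # the non-myelinated axon needs a strongly depolarized E_leak to offset Kv1
  e_ax <- calibrate_eleak(list(leak = 0.333, nav16 = 370, kv1 = 26.8, capq = 1), -70)
  expect_lt(abs(e_ax - (-38.3)), 2)
  # whole-preset calibration recovers the tabled values closely
  els <- calibrate_preset_eleaks(load_preset("NonMyelinated"))
  expect_lt(abs(els$axon - (-38.3)), 2)
  expect_lt(abs(els$somatodendritic - (-69.5)), 1)
})

test_that("every preset rests at -70 mV in soma and mid-axon", {
  for (nm in preset_names()) {
    mod <- cache_get_or(paste0("test_rest_model:", nm), function() {
      cfg <- morph_config(axon_length = 4000,
                          collateral_distances = c(128.5, 300.9),
                          collateral_lengths = 500, dend_diam = 9.37)
      discretize(build_default_morphology(cfg, load_preset(nm)$internode_target),
                 load_preset(nm))
    })
    r <- rest_state(mod)
    mid <- mod$node_comp[length(mod$node_comp) %/% 2]
    expect_lt(abs(r$V[mod$soma_comp] + 70), 0.5)
    expect_lt(abs(r$V[mid] + 70), 0.5)
  }
})
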