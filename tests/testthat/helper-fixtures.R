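# Shared fixtures. Heavy deterministic artifacts (calibrated configuration,
# full-size models, experiment runs) are memoized in the package session
# cache, so the first test file to need them pays the cost once.

# a preset with every voltage-gated conductance removed (passive membrane)
passive_preset <- function(leak = 0.333) {
  p <- load_preset("NonMyelinated")
  p$axon$leak <- leak
  p$axon$node[c("nav16", "kv1", "capq")] <- list(0, 0, 0)
  p$axon$internode[c("nav16", "kv1")] <- list(0, 0)
  p$axon$collateral[c("nav16", "kv1")] <- list(0, 0)
  p$axon$site_capq <- 0
  for (r in c("dendrite", "soma", "hillock")) {
    p$somatodendritic[[r]][c("nav12", "kdr")] <- list(0, 0)
    p$somatodendritic[[r]]$leak <- leak
  }
  p$somatodendritic$ais[c("nav12_from", "nav12_to", "nav16_from", "nav16_to", "kdr")] <-
    list(0, 0, 0, 0, 0)
  p$somatodendritic$ais$leak <- leak
  p
}

# a bare uniform passive cylinder (soma shrunk to the axon caliber)
passive_cable_morph <- function(axon_length = 20000, diam = 1.14) {
  cfg <- morph_config(
    axon_length = axon_length,
    collateral_distances = numeric(0), collateral_lengths = numeric(0),
    dend_length = 1, dend_diam = 0.01,
    soma_length = 1, soma_diam = diam,
    hillock_length = 1, hillock_diam = diam,
    ais_length = 1, ais_diam = diam
  )
  build_default_morphology(cfg, 100)
}

# small (short-axon) active morphology for solver-level tests
small_active_model <- function(preset = "NonMyelinated", internode_target = 100) {
  key <- paste0("test_small:", preset, ":", internode_target)
  cache_get_or(key, function() {
    cfg <- morph_config(
      axon_length = 4000, collateral_distances = c(128.5, 300.9),
      collateral_lengths = 500, dend_diam = 9.37
    )
    m <- build_default_morphology(cfg, internode_target)
    discretize(m, load_preset(preset))
  })
}

small_rest <- function(model) {
  key <- paste0("test_small_rest:", model$preset, ":", model$n)
  cache_get_or(key, function() rest_state(model))
}

# full-size experiment runs (shared across acceptance and property tests)
get_run <- function(preset, protocol) {
  cache_get_or(paste0("test_run:", preset, ":", protocol), function() {
    run_experiment(preset, protocol)
  })
}
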