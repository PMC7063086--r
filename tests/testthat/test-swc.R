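test_that("SWC round trip preserves lengths, diameters and topology", {
  m <- build_default_morphology()
  f <- tempfile(fileext = ".swc")
  write_swc(m, f)
  tab <- read_swc(f)
  expect_equal(sum(tab$parent == -1), 1) # single root
  # total cable length per type is preserved exactly
  s <- m$sections
  ax_len <- sum(s$length[s$role %in% c(
    "hillock", "ais", "main_axon_node", "main_axon_internode", "collateral"
  )])
  expect_equal(sum(tab$length[tab$role == "axon"]), ax_len, tolerance = 1e-9)
  expect_equal(sum(tab$length[tab$role == "dendrite"]), s$length[s$role == "dendrite"],
               tolerance = 1e-9)
  # diameters present in the file match the section diameters
  expect_setequal(round(unique(tab$diam), 6), round(unique(s$diam), 6))
  # branch count: ten collateral attachment points on the axon
  parents <- table(tab$parent[tab$parent > 0])
  expect_gte(sum(parents >= 2), 10)
})

test_that("presynaptic-site sidecar CSV round-trips", {
  m <- build_default_morphology()
  f <- tempfile(fileext = ".csv")
  write_sites_csv(m, f)
  back <- read_sites_csv(f)
  expect_equal(nrow(back), nrow(m$sites))
  expect_equal(back$path_distance, m$sites$path_distance)
  expect_equal(back$collateral_id, m$sites$collateral_id)
})
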