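ref_dists <- c(128.5, 129.6, 300.9, 301.5, 810.1, 993.9,
               1907.4, 2922.4, 3937.4, 4952.4)

test_that("default morphology realizes the reference geometry", {
  m <- build_default_morphology()
  s <- m$sections
  colls <- s[s$role == "collateral", ]
  expect_equal(nrow(colls), 10)
  expect_true(all(abs(sort(colls$path_start) - ref_dists) < 0.1))
  expect_equal(nrow(m$sites), 1982)
  expect_equal(unique(colls$diam), 0.23)
  expect_equal(unique(s$diam[s$role %in% c("main_axon_node", "main_axon_internode")]), 1.14)
  # main axon total span
  ax <- s[s$role %in% c("main_axon_node", "main_axon_internode"), ]
  expect_equal(max(ax$path_start + ax$length), 20000)
  # every role present, tree single-rooted and acyclic
  expect_setequal(
    unique(s$role),
    c("soma", "dendrite", "hillock", "ais", "main_axon_node",
      "main_axon_internode", "collateral")
  )
  expect_equal(sum(is.na(s$parent)), 1)
  expect_true(all(s$parent[!is.na(s$parent)] < s$id[!is.na(s$parent)]))
  expect_true(all(s$length > 0 & s$diam > 0))
})

test_that("first presynaptic site sits ~134 um from the soma", {
  m <- build_default_morphology()
  expect_lt(abs(min(m$sites$path_distance) - 134), 3)
})

test_that("internode layout hits the reference mean lengths", {
  m <- build_default_morphology()
  expect_equal(mean_internode_length(m), 101.1, tolerance = 1 / 101.1)
  m2 <- layout_internodes(m, 50)
  expect_equal(mean_internode_length(m2), 50.59, tolerance = 1 / 50.59)
  m4 <- layout_internodes(m, 25)
  expect_equal(mean_internode_length(m4), 25.35, tolerance = 1 / 25.35)
  # scaled layouts never move the collateral branch points
  for (mm in list(m2, m4)) {
    colls <- mm$sections[mm$sections$role == "collateral", ]
    expect_true(all(abs(sort(colls$path_start) - ref_dists) < 1e-9))
    expect_equal(nrow(mm$sites), 1982) # sites re-placed, count invariant
  }
  expect_error(layout_internodes(m, 1), "exceed")
})

test_that("degenerate configurations are handled", {
  # no collaterals, short axon: a plain soma+axon cable with no sites
  cfg <- morph_config(axon_length = 1000, collateral_distances = numeric(0),
                      collateral_lengths = numeric(0))
  m <- build_default_morphology(cfg)
  expect_equal(nrow(m$sites), 0)
  expect_equal(sum(m$sections$role == "collateral"), 0)
  # an unbranched 100 um axon is a single internode with no interior node
  cfg2 <- morph_config(axon_length = 100, collateral_distances = numeric(0),
                       collateral_lengths = numeric(0))
  m2 <- build_default_morphology(cfg2)
  expect_equal(sum(m2$sections$role == "main_axon_internode"), 1)
  expect_equal(sum(m2$sections$role == "main_axon_node"), 0)
  # collateral beyond the axon is rejected
  expect_error(
    build_default_morphology(morph_config(axon_length = 1000)),
    "exceeds the main axon length"
  )
})

test_that("site placement is floor(length/spacing) at midpoints", {
  cfg <- morph_config(axon_length = 2000, collateral_distances = 500,
                      collateral_lengths = 80)
  m <- build_default_morphology(cfg)
  expect_equal(nrow(m$sites), 10) # exact division
  expect_equal(m$sites$pos_on_collateral, (1:10 - 0.5) * 8)
  expect_equal(m$sites$path_distance, 500 + (1:10 - 0.5) * 8)
  # spacing larger than the collateral: zero sites, morphology still valid
  m0 <- place_presynaptic_sites(m, 200)
  expect_equal(nrow(m0$sites), 0)
  expect_error(place_presynaptic_sites(m, 0), "> 0")
})

test_that("path distances are additive along the tree", {
  m <- build_default_morphology()
  s <- m$sections
  coll <- s[s$role == "collateral", ][1, ]
  host <- s[s$id == coll$parent, ]
  expect_equal(
    path_distance(m, coll$id, 0.5),
    host$path_start + coll$parent_pos * host$length + 0.5 * coll$length,
    tolerance = 1e-9
  )
  # asserted site count is a config assertion, not silent trimming
  cfg <- default_morph_config()
  cfg$expected_sites <- 1000L
  expect_error(build_default_morphology(cfg), "asserts 1000")
})
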