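# Synthetic morphologies, SWC round trips and structural edits.

test_that("soma cylinder has sphere-equivalent lateral area", {
  s <- soma_cylinder(10)
  expect_equal(s$length, 10)
  expect_equal(s$lateral_area, 100 * pi)
  expect_equal(s$lateral_area, 4 * pi * 5^2) # sphere with the same diameter
  expect_equal(soma_cylinder(25)$lateral_area, 625 * pi)
  expect_error(soma_cylinder(-1), "positive")
})

test_that("generated large-field cells honour the requested field diameter", {
  m <- generate_rgc(191, seed = 1)
  fd <- dendritic_field_diameter(m)
  expect_gte(fd, 172) # within 10% of the 191 um request
  expect_lte(fd, 210)
  # a different request scales the tree
  fd2 <- dendritic_field_diameter(generate_rgc(120, seed = 1))
  expect_gt(fd2, 108); expect_lt(fd2, 132)
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_rgc(191, seed = 3)
  b <- generate_rgc(191, seed = 3)
  expect_identical(a$nodes, b$nodes)
  c <- generate_rgc(191, seed = 4)
  expect_false(identical(a$nodes, c$nodes))
  # the generator must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_rgc(100, seed = 5)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("midget cells keep all dendritic tips within the field radius", {
  m <- generate_rgc(50, midget = TRUE, seed = 2)
  dn <- m$nodes[m$nodes$region == "dendrite", ]
  expect_true(all(sqrt(dn$x^2 + dn$y^2) <= 25 + 2))
  expect_error(generate_rgc(-10), "positive")
  expect_error(generate_rgc(8, soma_diameter = 10), "exceed")
})

test_that("axonal labels follow path distance: hillock then AIS at 25-75 um", {
  m <- std_cell()
  d <- rgcstim:::path_distances(m)
  ax <- m$nodes$type == 2L
  expect_true(all(m$nodes$region[ax & d >= 25 & d <= 75] == "ais"))
  expect_true(all(m$nodes$region[ax & d < 25] == "hillock"))
  expect_true(all(m$nodes$region[ax & d > 75] == "axon"))
  expect_true(all(m$nodes$r > 0))
  expect_identical(sum(m$nodes$parent == 0L), 1L)
})

test_that("extend_axon adds exactly the requested collinear path length", {
  m <- generate_rgc(100, seed = 1, axon_length = 300)
  L0 <- rgcstim:::axon_path_length(m)
  m2 <- extend_axon(m, 900)
  expect_equal(rgcstim:::axon_path_length(m2), L0 + 900)
  expect_identical(extend_axon(m, 0), m)
  # terminal direction (0, 1, 0): extension is displaced 900 um along it
  nodes <- data.frame(type = c(1L, 2L, 2L), x = 0, y = c(0, 20, 60),
                      z = 0, r = c(5, 0.5, 0.5), parent = c(0L, 1L, 2L))
  me <- extend_axon(morphology(nodes), 900)
  tip <- me$nodes[nrow(me$nodes), ]
  expect_equal(c(tip$x, tip$y, tip$z), c(0, 960, 0))
  expect_equal(tip$r, 0.5)
  expect_error(extend_axon(soma_patch(), 900), "no axon")
})

test_that("dendrite removal deletes dendrites only; no-op without dendrites", {
  m <- std_cell()
  m2 <- edit_remove_dendrites(m)
  expect_identical(sum(m2$nodes$region == "dendrite"), 0L)
  kept <- m$nodes[m$nodes$region != "dendrite",
                  c("type", "x", "y", "z", "r")]
  got <- m2$nodes[, c("type", "x", "y", "z", "r")]
  rownames(kept) <- rownames(got) <- NULL
  expect_equal(got, kept)
  no_dend <- morphology(data.frame(type = c(1L, 2L), x = c(0, 30), y = 0,
                                   z = 0, r = c(5, 0.5), parent = c(0L, 1L)))
  expect_identical(edit_remove_dendrites(no_dend), no_dend)
})

test_that("proximal-axon shift translates the AIS with a continuous taper", {
  m <- std_cell()
  expect_identical(edit_shift_proximal_axon(m, dz = 0), m)
  m2 <- edit_shift_proximal_axon(m, first_len = 100, dz = -2)
  d <- rgcstim:::path_distances(m)
  ax <- which(m$nodes$type == 2L)
  s <- d[ax] - m$nodes$r[1]
  dz <- m2$nodes$z[ax] - m$nodes$z[ax]
  expect_true(all(abs(dz[s <= 100] - (-2)) < 1e-12))  # AIS moved by dz
  expect_true(all(abs(dz[s > 120]) < 1e-12))          # distal axon untouched
  mid <- s > 100 & s <= 120
  expect_true(all(dz[mid] > -2 & dz[mid] < 0))        # taper in between
  expect_true(all(m2$nodes$z[m$nodes$region == "dendrite"] ==
                    m$nodes$z[m$nodes$region == "dendrite"]))
  expect_error(edit_shift_proximal_axon(m, first_len = 0, dz = 1),
               "positive")
})

test_that("SWC write/read round trip is lossless", {
  m <- std_cell()
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, path)
  m2 <- read_swc(path)
  expect_identical(nrow(m2$nodes), nrow(m$nodes))
  expect_identical(m2$nodes$parent, m$nodes$parent)
  expect_identical(m2$nodes$region, m$nodes$region)
  for (cc in c("x", "y", "z", "r"))
    expect_lt(max(abs(m2$nodes[[cc]] - m$nodes[[cc]])), 1e-6)
})

test_that("SWC reader accepts a minimal file and rejects malformed trees", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# minimal", "1 1 0 0 0 5 -1", "2 3 10 0 0 1 1",
               "3 3 20 0 0 1 2"), path)
  m <- read_swc(path)
  expect_identical(nrow(m$nodes), 3L)
  expect_identical(m$nodes$region, c("soma", "dendrite", "dendrite"))

  writeLines(c("1 1 0 0 0 5 -1", "2 3 10 0 0 1 99"), path)
  expect_error(read_swc(path), "never defined")

  writeLines(c("1 1 0 0 0 5 -1", "2 3 10 0 0 1 3", "3 3 20 0 0 1 2"), path)
  expect_error(read_swc(path), "cycle")
})

test_that("segmentize splits sections below max_len and conserves area", {
  cab <- straight_cable(100, diam = 2, node_step = 100, type = 3L) # one section
  seg <- segmentize(cab, max_len = 12)
  ax <- seg$comp[seg$comp$region != "soma", ]
  expect_identical(nrow(ax), 9L)               # ceil(100/12)
  expect_true(all(abs(ax$len - 100 / 9) < 1e-9))
  expect_true(all(seg$comp$len < 12))
  # per-section area conserved under re-segmentation
  seg3 <- segmentize(cab, max_len = 4)
  expect_lt(abs(sum(seg3$comp$area) - sum(seg$comp$area)) /
              sum(seg$comp$area), 1e-3)
  # short section -> one compartment
  short <- segmentize(straight_cable(8, node_step = 8, type = 3L), 12)
  expect_identical(sum(short$comp$region != "soma"), 1L)
  # midpoints lie on the section geometry (here: the x axis)
  expect_true(all(abs(seg$comp$y) < 1e-12 & abs(seg$comp$z) < 1e-12))
})

test_that("a YAML study configuration materializes the package objects", {
  cfg <- load_study_config(system.file("extdata", "study_config.yaml",
                                       package = "rgcstim"))
  expect_s3_class(cfg$cell, "rgc_morphology")
  expect_equal(dendritic_field_diameter(cfg$cell), 191, tolerance = 0.1)
  expect_equal(cfg$electrode$a, 10)
  expect_equal(cfg$electrode$rs, 0.725)
  expect_equal(pulse_current(cfg$pulse, 1.05), -1.5)
  expect_identical(nrow(cfg$grid), 15L * 7L)
  expect_equal(cfg$search$tol, 0.1)
  expect_null(cfg$profile)
  expect_error(load_study_config("no/such/file.yaml"), "not found")
})
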